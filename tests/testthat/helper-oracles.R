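# Independent literal transcriptions of the evaluation formulas, written as
# explicit loops over patients and time points. These deliberately share no
# code with the package implementation and serve as the oracle side of the
# metric equivalence tests.
#
# `patients` is a list of lists: each element has numeric vectors `truth` and
# `pred` of equal length (the patient's observed future points) and a scalar
# `v0`.

oracle_mae <- function(patients) {
  n <- length(patients)
  total <- 0
  for (p in patients) {
    Ti <- length(p$truth)
    inner <- 0
    for (t in seq_len(Ti)) inner <- inner + abs(p$truth[t] - p$pred[t])
    total <- total + inner / Ti
  }
  total / n
}

oracle_mase <- function(patients) {
  num <- oracle_mae(patients)
  n <- length(patients)
  denom <- 0
  for (p in patients) {
    Ti <- length(p$truth)
    inner <- 0
    for (t in seq_len(Ti)) inner <- inner + abs(p$truth[t] - p$v0)
    denom <- denom + inner / Ti
  }
  num / (denom / n)
}

oracle_smape <- function(patients) {
  n <- length(patients)
  total <- 0
  for (p in patients) {
    Ti <- length(p$truth)
    inner <- 0
    for (t in seq_len(Ti)) {
      d <- abs(p$truth[t]) + abs(p$pred[t])
      if (d != 0) inner <- inner + abs(p$truth[t] - p$pred[t]) / d
    }
    total <- total + inner / Ti
  }
  200 * total / n
}

oracle_spearman <- function(patients) {
  truth_all <- unlist(lapply(patients, `[[`, "truth"))
  pred_all <- unlist(lapply(patients, `[[`, "pred"))
  Rv <- rank(truth_all, ties.method = "average")
  Rp <- rank(pred_all, ties.method = "average")
  n <- length(patients)
  # mean ranks per the equation
  idx <- 0L
  mRv <- 0; mRp <- 0
  for (p in patients) {
    Ti <- length(p$truth)
    for (t in seq_len(Ti)) {
      idx <- idx + 1L
      mRv <- mRv + Rv[idx] / Ti
      mRp <- mRp + Rp[idx] / Ti
    }
  }
  mRv <- mRv / n; mRp <- mRp / n
  idx <- 0L
  num <- 0; dv <- 0; dp <- 0
  for (p in patients) {
    Ti <- length(p$truth)
    for (t in seq_len(Ti)) {
      idx <- idx + 1L
      num <- num + (Rv[idx] - mRv) * (Rp[idx] - mRp) / Ti
      dv <- dv + (Rv[idx] - mRv)^2 / Ti
      dp <- dp + (Rp[idx] - mRp)^2 / Ti
    }
  }
  num / sqrt(dv * dp)
}

# Brute-force ROC AUC by pair counting with half credit for ties.
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  wins <- 0
  for (a in pos) {
    for (b in neg) {
      if (a > b) wins <- wins + 1
      else if (a == b) wins <- wins + 0.5
    }
  }
  wins / (length(pos) * length(neg))
}

oracle_label <- function(v, vmin, vmax) {
  if (v < vmin) "low" else if (v > vmax) "high" else "normal"
}

oracle_auc_reference <- function(pred, truth, vmin, vmax) {
  labels <- vapply(truth, oracle_label, character(1), vmin = vmin, vmax = vmax)
  counts <- c(low = sum(labels == "low"), normal = sum(labels == "normal"),
              high = sum(labels == "high"))
  a_low <- oracle_auc(vmin - pred, labels == "low")
  a_high <- oracle_auc(pred - vmax, labels == "high")
  a_norm <- oracle_auc(pmin(pred - vmin, vmax - pred), labels == "normal")
  aucs <- c(low = a_low, normal = a_norm, high = a_high)
  avail <- !is.na(aucs) & counts > 0
  weighted <- if (any(avail)) sum(aucs[avail] * counts[avail]) / sum(counts[avail]) else NA_real_
  list(low = a_low, high = a_high, normal = a_norm, weighted = weighted)
}

# Brute-force trend label: point at time tt labeled from the s consecutive
# pairs ending at tt; values given on an integer time grid as named vector.
oracle_trend_label <- function(traj, tt, s) {
  if (tt < s) return("excluded")
  dec <- TRUE; inc <- TRUE
  for (k in (tt - s):(tt - 1)) {
    a <- traj[as.character(k)]
    b <- traj[as.character(k + 1)]
    if (is.na(a) || is.na(b)) return("excluded")
    if (!(b < a)) dec <- FALSE
    if (!(b > a)) inc <- FALSE
  }
  if (dec) "decreasing" else if (inc) "increasing" else "neither"
}

oracle_trend_score <- function(traj, tt, s, direction) {
  if (tt < s) return(NA_real_)
  worst <- Inf
  for (k in (tt - s):(tt - 1)) {
    a <- traj[as.character(k)]
    b <- traj[as.character(k + 1)]
    if (is.na(a) || is.na(b)) return(NA_real_)
    margin <- direction * (a - b)
    if (margin < worst) worst <- margin
  }
  worst
}

oracle_ks <- function(x, y) {
  best <- 0
  for (g in c(x, y)) {
    d <- abs(sum(x <= g) / length(x) - sum(y <= g) / length(y))
    if (d > best) best <- d
  }
  best
}
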