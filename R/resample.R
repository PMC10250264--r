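# Internal plumbing between trial tables and the compiled resampling engine.
# A "resample frame" lays trials out contiguously by participant x stratum
# and remembers which strata belong to which participant and condition.

# `trials` may carry a 0/1 `valid` column; absent, all trials count
resample_frame <- function(trials, stratify_by = c("condition", "direction")) {
  dt <- as.data.table(trials)
  need <- unique(c("participant", "condition", "rt_ms", stratify_by))
  missing <- setdiff(need, names(dt))
  if (length(missing)) {
    stopf("stratification columns absent from data: %s",
          paste(missing, collapse = ", "))
  }
  if (!"condition" %in% stratify_by) {
    stopf("strata must at least separate the two conditions")
  }
  if (!"valid" %in% names(dt)) dt[, valid := 1]
  dt[, stratum := do.call(paste, c(.SD, sep = "|")), .SDcols = stratify_by]
  setorder(dt, participant, stratum)
  grp <- dt[, list(size = .N,
                   pid = participant[1L],
                   inc = condition[1L] == "incongruent"),
            by = c("participant", "stratum")]
  starts <- cumsum(c(0L, grp$size[-nrow(grp)]))
  pid_levels <- unique(grp$pid)
  list(
    x = dt$rt_ms,
    w = as.numeric(dt$valid),
    grp_start = as.integer(starts),
    grp_size = as.integer(grp$size),
    g_pid = match(grp$pid, pid_levels),
    g_inc = grp$inc,
    pid_levels = pid_levels,
    n_participants = length(pid_levels)
  )
}

# run the engine: k_per_stratum = 0 uses whole strata
engine_halves <- function(fr, k_per_stratum, n_reps, method,
                          mc_full_size = FALSE) {
  k <- rep.int(as.integer(k_per_stratum), length(fr$grp_size))
  if (any(k > fr$grp_size)) {
    stopf("requested %d trials per stratum but a stratum has only %d",
          k_per_stratum, min(fr$grp_size[k > fr$grp_size]))
  }
  resample_halves_cpp(fr$x, fr$w, fr$grp_start, fr$grp_size, k,
                      as.integer(n_reps), as.integer(method), mc_full_size)
}

# collapse per-(participant x stratum) half sums into per-participant
# flanker effects, one column per replication; NaN where a condition half
# holds no valid trial
half_effects <- function(sums, cnts, fr) {
  eff_part <- function(inc) {
    sel <- fr$g_inc == inc
    s <- rowsum(sums[sel, , drop = FALSE], fr$g_pid[sel])
    c <- rowsum(cnts[sel, , drop = FALSE], fr$g_pid[sel])
    full_s <- matrix(NA_real_, fr$n_participants, ncol(sums))
    full_c <- matrix(0, fr$n_participants, ncol(sums))
    ord <- as.integer(rownames(s))
    full_s[ord, ] <- s
    full_c[ord, ] <- c
    full_s / ifelse(full_c > 0, full_c, NA_real_)
  }
  eff_part(TRUE) - eff_part(FALSE)
}

# per-column Pearson correlation of two matrices, pairwise-complete;
# NaN for columns with < 3 complete pairs or zero variance
col_cors <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (all(ok)) {
    n <- nrow(a)
    ma <- colMeans(a); mb <- colMeans(b)
    va <- colMeans(a * a) - ma^2
    vb <- colMeans(b * b) - mb^2
    cov <- colMeans(a * b) - ma * mb
    den <- sqrt(va * vb)
    ifelse(den > 0, cov / den, NaN)
  } else {
    vapply(seq_len(ncol(a)), function(j) {
      use <- ok[, j]
      if (sum(use) < 3L) return(NaN)
      x <- a[use, j]; y <- b[use, j]
      if (var(x) == 0 || var(y) == 0) return(NaN)
      cor(x, y)
    }, numeric(1))
  }
}

# aggregate replication coefficients: simple mean or back-transformed mean
# of Fisher z values (coefficients at +/-1 are nudged inside the domain)
aggregate_coefs <- function(r, how = c("mean", "fisher_mean")) {
  how <- match.arg(how)
  r <- r[is.finite(r)]
  if (!length(r)) return(NaN)
  if (how == "mean") return(mean(r))
  z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  tanh(mean(z))
}
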