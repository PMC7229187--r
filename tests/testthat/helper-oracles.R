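# Independent oracles used across the suite. Each re-derives the quantity
# under test by a different route (dense brute force, closed form, or a
# reference routine from the survival stack) so implementation and check
# never share code.

# Single-linkage components at threshold `link` via hierarchical
# clustering on the dense distance matrix.
oracle_components <- function(xy, link) {
  if (nrow(xy) < 2) return(seq_len(nrow(xy)))
  hc <- stats::hclust(stats::dist(xy), method = "single")
  unname(stats::cutree(hc, h = link))
}

# Brute-force proximity counts with explicit sqrt distances.
oracle_count_within <- function(src, tgt, r) {
  if (nrow(tgt) == 0) return(integer(0))
  vapply(seq_len(nrow(tgt)), function(i) {
    if (nrow(src) == 0) return(0L)
    d <- sqrt((src[, 1] - tgt[i, 1])^2 + (src[, 2] - tgt[i, 2])^2)
    sum(d <= r)
  }, 0L)
}

# Newton-Raphson on the Cox partial likelihood for one covariate,
# untied data (Breslow = Efron = exact in that case).
oracle_cox_newton <- function(time, event, x, tol = 1e-12) {
  beta <- 0
  for (it in 1:200) {
    U <- 0
    I <- 0
    for (i in which(event == 1)) {
      R <- which(time >= time[i])
      w <- exp(beta * x[R])
      s0 <- sum(w)
      s1 <- sum(w * x[R])
      s2 <- sum(w * x[R]^2)
      U <- U + x[i] - s1 / s0
      I <- I + s2 / s0 - (s1 / s0)^2
    }
    step <- U / I
    step <- sign(step) * min(abs(step), 1)  # damped Newton
    beta <- beta + step
    if (abs(step) < tol) break
  }
  beta
}

# Exhaustive maximally selected log-rank scan via survival::survdiff.
oracle_cutpoint_scan <- function(values, time, event, min_group_prop = 0.1) {
  n <- length(values)
  uv <- sort(unique(values))
  cands <- (uv[-1] + uv[-length(uv)]) / 2
  cands <- cands[vapply(cands, function(c) {
    a <- sum(values > c)
    a >= min_group_prop * n && (n - a) >= min_group_prop * n
  }, logical(1))]
  zs <- vapply(cands, function(c) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ I(values > c))
    sqrt(sd$chisq)
  }, 0)
  list(cutoff = cands[which.max(zs)], z = max(zs))
}

# Square-tumor / straight-front analytic case: 2000x2000 um tumor whose
# top edge is the invasive front; tissue extent reaches 1000 um beyond.
square_case <- function(side = 2000) {
  list(tumor = rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)),
       front = rbind(c(0, 0), c(side, 0)),
       extent = c(0, side, -1000, side))
}

# A small untied 6-subject survival dataset for exact Cox checks (the
# covariate is deliberately not monotone in the death order, so the
# partial likelihood has a finite maximizer).
six_subject_data <- function() {
  data.frame(time_months = c(1.1, 2.3, 3.7, 4.9, 6.2, 7.8),
             event = c(1L, 0L, 1L, 1L, 0L, 1L),
             x = c(0.5, 2.0, -1.0, 1.0, -0.5, 0.3))
}

# Fast synthetic-config variant for tests that only need structure, not
# cohort-scale realism.
small_synth <- function(...) {
  base <- list(extent_um = c(1000, 1000), front_depth_um = 300,
               bud_mean_count = 6, n_patients = 10L)
  do.call(synth_config, utils::modifyList(base, list(...)))
}
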