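# Independent brute-force oracles used to cross-check the package's
# statistics, plus small fixture builders. Everything here is written
# from the definitions, not by calling the implementation under test.

# Benjamini-Hochberg step-up by the definition: sort ascending,
# q_(i) = min_{j >= i} p_(j) * m / j, cap at 1, map back.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m), 1)
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# one-way fixed-effects ANOVA from sums of squares, one probe at a time
anova_oracle <- function(groups) {
  # groups: list of numeric vectors, one per group
  k <- length(groups)
  n <- sum(lengths(groups))
  grand <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssb == 0) return(list(F = 0, p = 1))
  if (ssw == 0) return(list(F = Inf, p = 0))
  Fv <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = Fv, p = pf(Fv, k - 1, n - k, lower.tail = FALSE))
}

# exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled ranks to sample a (no ties assumed)
mw_enum_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  ua_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  splits <- utils::combn(na + nb, na)
  ua_all <- apply(splits, 2, function(idx) {
    sum(rank(pooled)[idx]) - na * (na + 1) / 2
  })
  p <- 2 * min(mean(ua_all <= ua_obs), mean(ua_all >= ua_obs))
  list(U = min(ua_obs, na * nb - ua_obs), p = min(p, 1))
}

# argmax-by-loop Pearson template matching with the documented
# tie-break: templates arrive in preference order, first max wins
pearson_argmax_oracle <- function(means, template_df) {
  rs <- vapply(seq_len(nrow(template_df)), function(i) {
    suppressWarnings(cor(means, as.numeric(template_df[i, c("ES", "OS", "CSE")])))
  }, numeric(1))
  which.max(rs)
}

# build an expr_matrix directly on the log2 scale for statistics tests
log2_matrix <- function(values, probe_ids = sprintf("p%d", seq_len(nrow(values))),
                        sample_ids = sprintf("s%d", seq_len(ncol(values))),
                        stage = "filtered") {
  dimnames(values) <- list(probe_ids, sample_ids)
  m <- expr_matrix(values, scale = "linear", stage = stage)
  m$scale <- "log2"
  m
}

# a minimal balanced three-group sheet
three_group_sheet <- function(n_es = 2, n_os = 2, n_cse = 2) {
  sample_sheet(
    sample_id = c(sprintf("ES_%d", seq_len(n_es)),
                  sprintf("OS_%d", seq_len(n_os)),
                  sprintf("CSE_%d", seq_len(n_cse))),
    group = c(rep("ES", n_es), rep("OS", n_os), rep("CSE", n_cse)))
}

# small default-shaped simulation, scaled for unit tests
small_config <- function(n_probes = 2000, per_pattern = 25L, seed = 1L, ...) {
  simulation_config(
    n_probes = n_probes, n_neg_controls = 200,
    planted = setNames(rep(per_pattern, 6),
                       generate_templates("binary6")$templates$name),
    seed = seed, ...)
}

write_feature_file <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}
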