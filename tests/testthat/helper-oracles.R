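# Independent oracles and small generators shared across tests.

# per-hit predicate evaluated one threshold at a time, independently of
# the vectorised implementation in filter_hits()
brute_force_keep <- function(hit, criteria) {
  cmp_lt <- function(a, b) if (criteria$strict) a < b else a <= b
  cmp_gt <- function(a, b) if (criteria$strict) a > b else a >= b
  ok <- TRUE
  if (!cmp_lt(hit$evalue, criteria$max_evalue)) ok <- FALSE
  if (!cmp_gt(hit$pct_identity, criteria$min_identity)) ok <- FALSE
  if (!cmp_gt(hit$aln_length, criteria$min_length)) ok <- FALSE
  if (!is.null(criteria$min_score) && !cmp_gt(hit$score, criteria$min_score)) {
    ok <- FALSE
  }
  ok
}

# random hit table whose values straddle both rule sets' thresholds,
# including exact boundary values
random_hits <- function(n, seed = 42) {
  withr::with_seed(seed, {
    boundary <- function(vals, random) {
      out <- random
      k <- max(1, n %/% 10)
      idx <- sample.int(n, min(length(vals) * k, n))
      out[idx] <- rep(vals, length.out = length(idx))
      out
    }
    tibble::tibble(
      query_id = sprintf("q%04d", sample.int(n, n, replace = TRUE)),
      subject_id = sprintf("s%04d", seq_len(n)),
      pct_identity = boundary(c(80, 90), runif(n, 60, 100)),
      aln_length = as.integer(boundary(c(50, 100, 51, 101),
                                       sample(20:400, n, replace = TRUE))),
      evalue = boundary(c(1e-5, 1e-4), 10^runif(n, -40, 0)),
      score = boundary(c(80), runif(n, 10, 300))
    )
  })
}

# two-sided Fisher exact p by exhaustive enumeration of all tables with
# the observed margins, using choose() directly
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[xs == a]
  # same "almost equal" relation fisher.test uses for two-sided mass
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# one-tailed pooled-variance two-sample t, computed from the textbook
# formulas (H1: mean(x) < mean(y))
t_pooled_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  pt(tstat, nx + ny - 2)
}

# minimal well-formed gene table for classifier tests
tiny_genes <- function(ids_x = character(), ids_y = character()) {
  tibble::tibble(
    gene_id = c(ids_x, ids_y),
    species = "latifolia",
    linkage = c(rep("X", length(ids_x)), rep("Y", length(ids_y))),
    is_probe = FALSE,
    bac_id = "bac01"
  )
}
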