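#' Estimate the RNA-seq false-negative rate from tester genes
#'
#' Tester genes are independently validated X/Y gene pairs. Among testers
#' expressed in the assayed tissue (matching at least one RNA-seq
#' contig), the false-negative rate (FNR) is the fraction not ascertained
#' as sex-linked by any of the combined studies. Unexpressed testers
#' carry no information about detection given expression and enter only
#' the expressed fraction.
#'
#' @param testers Tibble with logical columns `expressed` and
#'   `detected_sexlinked` (see [read_tester_table()]).
#' @return One-row tibble: `n_testers`, `n_expressed`, `prop_expressed`,
#'   `n_undetected`, `fnr`.
#' @examples
#' testers <- tibble::tibble(expressed = c(TRUE, TRUE, TRUE, TRUE),
#'                           detected_sexlinked = c(TRUE, TRUE, TRUE, FALSE))
#' estimate_fnr(testers) # fnr 0.25
#' @export
estimate_fnr <- function(testers) {
  check_that(
    "`testers` needs logical columns expressed, detected_sexlinked" =
      all(c("expressed", "detected_sexlinked") %in% names(testers)),
    "detected_sexlinked implies expressed" =
      all(testers$expressed | !testers$detected_sexlinked),
    "at least one expressed tester is required" = any(testers$expressed)
  )
  expr <- testers[testers$expressed, , drop = FALSE]
  tibble(
    n_testers = nrow(testers),
    n_expressed = nrow(expr),
    prop_expressed = nrow(expr) / nrow(testers),
    n_undetected = sum(!expr$detected_sexlinked),
    fnr = sum(!expr$detected_sexlinked) / nrow(expr)
  )
}

#' Partition undetected genes into missed pairs and hemizygotes
#'
#' Of `n_undetected` expressed genes not ascertained as sex-linked,
#' `fnr * n_expressed` are expected to be true X/Y pairs the combined
#' studies simply missed; the remainder are probably hemizygous genes
#' whose partner copy is genuinely absent. The two components sum to
#' `n_undetected` exactly; a negative remainder (possible when the FNR
#' is large relative to the undetected count) is clipped to zero with a
#' warning.
#'
#' @param n_undetected Expressed genes not ascertained sex-linked (U).
#' @param fnr False-negative rate `f` in `[0, 1]`.
#' @param n_expressed Expressed genes retained for analysis (E >= U).
#' @return One-row tibble: `expected_xy_undetected` (`f * E`) and
#'   `undetected_hemi` (`U - f * E`, clipped at 0).
#' @examples
#' correct_counts(22, 0.25, 43) # 10.75 missed pairs, 11.25 hemizygous
#' @export
correct_counts <- function(n_undetected, fnr, n_expressed) {
  check_that(
    "`fnr` must lie in [0, 1]" = fnr >= 0 && fnr <= 1,
    "`n_undetected` must be non-negative" = n_undetected >= 0
  )
  if (n_undetected > n_expressed) {
    abort("`n_undetected` cannot exceed `n_expressed`")
  }
  expected <- fnr * n_expressed
  hemi <- n_undetected - expected
  if (hemi < 0) {
    warn(sprintf(
      "expected undetected pairs (%.2f) exceed undetected genes (%g); hemizygous remainder clipped to 0",
      expected, n_undetected))
    hemi <- 0
  }
  tibble(expected_xy_undetected = expected, undetected_hemi = hemi)
}

#' Corrected loss proportion
#'
#' Total inferred hemizygous genes (detected plus the undetected
#' remainder from [correct_counts()]) over the number of ancestral genes,
#' as a percentage. `n_hemi_excluded` removes anomalous detected calls
#' from the numerator (e.g. the contradictory X-hemizygous label on a
#' Y-linked gene).
#'
#' @param n_hemi_detected Genes detected as hemizygous (H).
#' @param undetected_hemi Undetected hemizygous remainder (real).
#' @param n_ancestral Ancestral-gene denominator (A > 0).
#' @param n_hemi_excluded Detected hemizygous calls to drop (default 0).
#' @param rounded Round half-up to integer percent (default); `FALSE`
#'   returns the exact percentage.
#' @return Loss percentage.
#' @examples
#' loss_proportion(5, 11.25, 50) # 33 (16.25 / 50)
#' loss_proportion(1, 2.25, 50, n_hemi_excluded = 1) # 5 (2.25 / 50)
#' @export
loss_proportion <- function(n_hemi_detected, undetected_hemi, n_ancestral,
                            n_hemi_excluded = 0, rounded = TRUE) {
  check_that(
    "`n_ancestral` must be > 0" = n_ancestral > 0,
    "`n_hemi_excluded` cannot exceed `n_hemi_detected`" =
      n_hemi_excluded <= n_hemi_detected
  )
  total <- (n_hemi_detected - n_hemi_excluded) + undetected_hemi
  pct <- 100 * total / n_ancestral
  if (rounded) round_half_up(pct) else pct
}

#' Contrast Y-side and X-side gene loss by Fisher's exact test
#'
#' Two-by-two exact test of lost vs retained genes between the Y and X
#' analyses. Fractional corrected counts are rounded half-up to integers
#' (exact tests need integer tables); the test is two-sided.
#'
#' @param y_lost,y_total Lost count (possibly fractional) and ancestral
#'   total for the Y-side analysis.
#' @param x_lost,x_total Same for the X side.
#' @return One-row tibble: the integer table cells and `p_value`.
#' @export
contrast_xy_loss <- function(y_lost, y_total, x_lost, x_total) {
  check_that(
    "totals must be > 0" = y_total > 0 && x_total > 0,
    "lost counts must be non-negative" = y_lost >= 0 && x_lost >= 0,
    "lost counts cannot exceed totals" = y_lost <= y_total && x_lost <= x_total
  )
  yl <- round_half_up(y_lost)
  xl <- round_half_up(x_lost)
  tab <- matrix(c(yl, y_total - yl, xl, x_total - xl), nrow = 2,
                dimnames = list(c("lost", "retained"), c("Y", "X")))
  tibble(y_lost = yl, y_retained = y_total - yl,
         x_lost = xl, x_retained = x_total - xl,
         p_value = stats::fisher.test(tab)$p.value)
}

#' Compare expression between detected and undetected genes
#'
#' One-tailed two-sample t test of the hypothesis that genes not
#' ascertained as sex-linked have lower mean expression than ascertained
#' ones (H1: mean(undetected) < mean(detected)). The classical
#' equal-variance Student test is the default; `equal_var = FALSE` uses
#' Welch's approximation. With fewer than two values in either group the
#' p-value is `NA` and the means are still reported.
#'
#' @param rpkm_detected,rpkm_undetected Numeric expression vectors
#'   (RPKM), both non-empty.
#' @param equal_var Pool the variances (default `TRUE`).
#' @return One-row tibble: `mean_detected`, `mean_undetected`,
#'   `statistic`, `df`, `p_value`.
#' @export
compare_expression <- function(rpkm_detected, rpkm_undetected,
                               equal_var = TRUE) {
  check_that(
    "both groups must be non-empty" =
      length(rpkm_detected) > 0 && length(rpkm_undetected) > 0
  )
  out <- tibble(mean_detected = mean(rpkm_detected),
                mean_undetected = mean(rpkm_undetected),
                statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  if (length(rpkm_detected) < 2 || length(rpkm_undetected) < 2) {
    return(out)
  }
  tt <- stats::t.test(rpkm_undetected, rpkm_detected,
                      alternative = "less", var.equal = equal_var)
  out$statistic <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p_value <- tt$p.value
  out
}

side_estimate <- function(tab_row, fnr, method) {
  cc <- correct_counts(tab_row$n_undetected, fnr, tab_row$n_retained)
  total_paper <- (tab_row$n_hemi - tab_row$n_hemi_excluded) + cc$undetected_hemi
  total <- if (method == "fnr_consistent" && fnr < 1) {
    total_paper / (1 - fnr)
  } else {
    total_paper
  }
  tibble(
    linkage = tab_row$linkage,
    n_total = tab_row$n_total, n_no_match = tab_row$n_no_match,
    n_expressed = tab_row$n_retained,
    n_xy = tab_row$n_xy, n_hemi = tab_row$n_hemi,
    n_hemi_excluded = tab_row$n_hemi_excluded,
    n_undetected = tab_row$n_undetected,
    expected_xy_undetected = cc$expected_xy_undetected,
    undetected_hemi = cc$undetected_hemi,
    total_hemi = total
  )
}

#' Ascertainment-corrected gene-loss estimate
#'
#' The central estimator. Per linkage side (X-linked genes measure loss
#' from the Y; Y-linked genes measure loss from the X) it takes the
#' category tabulation of the new (non-probe) genes, partitions the
#' undetected genes with [correct_counts()] at the tester-estimated FNR,
#' forms the total inferred hemizygous count, and divides by the number
#' of ancestral genes — the expressed new genes of both linkages
#' (`n_ancestral`), or additionally the probe gene families
#' (`n_ancestral_incl_probes`). The X-vs-Y contrast is tested with
#' [contrast_xy_loss()].
#'
#' @param combined Per-gene classification from [classify_genes()].
#' @param genes Validated gene table.
#' @param testers Optional tester table; its FNR is estimated with
#'   [estimate_fnr()]. Supply `fnr` directly instead if preferred.
#' @param fnr False-negative rate; overrides `testers` when given.
#' @param exclude_anomalous Drop anomalous detected hemizygous calls
#'   (Y-linked genes labelled X-hemizygous) from the numerator (default
#'   `TRUE`).
#' @param method `"paper"` applies the correction `f * E` with all
#'   expressed genes in `E` (the table-reproduction arithmetic, which
#'   slightly overstates missed pairs because hemizygous genes cannot be
#'   missed X/Y pairs); `"fnr_consistent"` solves the self-consistent
#'   count `H_true = (H + U - f * E) / (1 - f)`, which removes that
#'   overstatement and is the mode validated by parameter recovery.
#' @return An object of class `loss_estimate`; see [tidy.loss_estimate()]
#'   and [glance.loss_estimate()].
#' @export
estimate_loss <- function(combined, genes, testers = NULL, fnr = NULL,
                          exclude_anomalous = TRUE,
                          method = c("paper", "fnr_consistent")) {
  method <- match.arg(method)
  genes <- validate_gene_table(genes)
  if (is.null(fnr)) {
    check_that("supply either `testers` or `fnr`" = !is.null(testers))
    fnr_tbl <- estimate_fnr(testers)
    fnr <- fnr_tbl$fnr
  } else {
    check_that("`fnr` must lie in [0, 1]" = fnr >= 0 && fnr <= 1)
    fnr_tbl <- tibble(n_testers = NA_integer_, n_expressed = NA_integer_,
                      prop_expressed = NA_real_, n_undetected = NA_integer_,
                      fnr = fnr)
  }
  tab <- tabulate_categories(combined, genes, probes = "exclude") %>%
    mutate(n_hemi_excluded = if (exclude_anomalous) .data$n_anomalous_hemi else 0L)
  # a side without genes (e.g. no Y-linked genes sampled) contributes zeros
  for (side in setdiff(c("X", "Y"), tab$linkage)) {
    tab <- bind_rows(tab, tibble(
      linkage = side, n_total = 0L, n_no_match = 0L, n_retained = 0L,
      n_xy = 0L, n_hemi = 0L, n_undetected = 0L, n_anomalous_hemi = 0L,
      n_hemi_excluded = 0L))
  }
  sides <- purrr::map(c("X", "Y"),
                      ~ side_estimate(filter(tab, .data$linkage == .x),
                                      fnr, method)) %>%
    bind_rows()
  n_ancestral <- sum(sides$n_expressed)
  focal <- filter(genes, .data$species == "latifolia", .data$is_probe)
  n_probe_families <- n_distinct(focal$probe_family[!is.na(focal$probe_family)])
  if (nrow(focal) > 0 && n_probe_families == 0) {
    warn("probe genes lack probe_family tags; counting each probe entry as one ancestral gene")
    n_probe_families <- nrow(focal)
  }
  n_ancestral_incl <- n_ancestral + n_probe_families
  sides <- sides %>%
    mutate(
      lost_from = if_else(.data$linkage == "X", "Y", "X"),
      loss_prop = .data$total_hemi / n_ancestral,
      loss_pct = round_half_up(100 * .data$total_hemi / n_ancestral),
      loss_prop_incl_probes = .data$total_hemi / n_ancestral_incl,
      loss_pct_incl_probes = round_half_up(100 * .data$total_hemi / n_ancestral_incl)
    )
  x_side <- filter(sides, .data$linkage == "X")
  y_side <- filter(sides, .data$linkage == "Y")
  fisher <- contrast_xy_loss(x_side$total_hemi, n_ancestral,
                             y_side$total_hemi, n_ancestral)
  structure(
    list(sides = sides, fnr = fnr_tbl, n_ancestral = n_ancestral,
         n_ancestral_incl_probes = n_ancestral_incl,
         method = method, exclude_anomalous = exclude_anomalous,
         fisher = fisher),
    class = "loss_estimate"
  )
}

#' Re-run the loss estimate on outgroup-anchored genes only
#'
#' Restricts the gene set to genes with a homolog in the outgroup
#' species, which must have been present on the ancestral proto-sex
#' chromosomes — excluding genes gained by the sex chromosomes after
#' their origin, whose "loss" is not meaningful.
#'
#' @inheritParams estimate_loss
#' @param ... Passed to [estimate_loss()].
#' @return A `loss_estimate` on the restricted subset.
#' @export
restrict_to_outgroup <- function(combined, genes, ...) {
  genes <- validate_gene_table(genes)
  keep <- filter(genes, .data$species != "latifolia" |
                   (!is.na(.data$has_outgroup_homolog) & .data$has_outgroup_homolog))
  check_that("no genes with outgroup homologs in the table" =
               any(keep$species == "latifolia"))
  combined_sub <- filter(combined, .data$gene_id %in% keep$gene_id)
  estimate_loss(combined_sub, keep, ...)
}

#' @export
print.loss_estimate <- function(x, ...) {
  cat("Ascertainment-corrected gene-loss estimate (method: ", x$method,
      ")\n", sep = "")
  cat("FNR: ", format(x$fnr$fnr), "   ancestral genes: ", x$n_ancestral,
      " (", x$n_ancestral_incl_probes, " incl. probes)\n\n", sep = "")
  for (i in seq_len(nrow(x$sides))) {
    s <- x$sides[i, ]
    cat(sprintf(
      "Loss from %s (among %s-linked genes): %g detected + %.2f undetected hemizygous = %.2f / %d -> %d %% (%d %% incl. probes)\n",
      s$lost_from, s$linkage, s$n_hemi - s$n_hemi_excluded,
      s$undetected_hemi, s$total_hemi, x$n_ancestral, s$loss_pct,
      s$loss_pct_incl_probes))
  }
  cat(sprintf("\nFisher's exact X-vs-Y contrast: p = %.3g\n",
              x$fisher$p_value))
  invisible(x)
}

#' Tidy a loss estimate
#'
#' @param x A `loss_estimate`.
#' @param ... Unused.
#' @return One row per linkage side with counts, corrected components and
#'   loss percentages.
#' @export
tidy.loss_estimate <- function(x, ...) x$sides

#' One-row summary of a loss estimate
#'
#' @param x A `loss_estimate`.
#' @param ... Unused.
#' @return One-row tibble: FNR, denominators, per-side loss percentages
#'   and the Fisher contrast p-value.
#' @export
glance.loss_estimate <- function(x, ...) {
  xs <- filter(x$sides, .data$linkage == "X")
  ys <- filter(x$sides, .data$linkage == "Y")
  tibble(
    fnr = x$fnr$fnr,
    n_ancestral = x$n_ancestral,
    n_ancestral_incl_probes = x$n_ancestral_incl_probes,
    loss_y_pct = xs$loss_pct,
    loss_y_pct_incl_probes = xs$loss_pct_incl_probes,
    loss_x_pct = ys$loss_pct,
    loss_x_pct_incl_probes = ys$loss_pct_incl_probes,
    fisher_p = x$fisher$p_value,
    method = x$method
  )
}

#' Plot a loss estimate
#'
#' Stacked bars of the expressed-gene categories per linkage side, with
#' the corrected undetected-hemizygous remainder shown as its own
#' segment.
#'
#' @param object A `loss_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loss_estimate <- function(object, ...) {
  seg <- object$sides %>%
    mutate(side = paste0(.data$linkage, "-linked genes\n(loss from ",
                         .data$lost_from, ")")) %>%
    select("side", xy_pair_detected = "n_xy",
           hemizygous_detected = "n_hemi",
           missed_xy_pair = "expected_xy_undetected",
           hemizygous_undetected = "undetected_hemi") %>%
    tidyr::pivot_longer(-"side", names_to = "component", values_to = "genes") %>%
    mutate(component = factor(.data$component,
                              levels = c("xy_pair_detected", "missed_xy_pair",
                                         "hemizygous_detected",
                                         "hemizygous_undetected")))
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$side, y = .data$genes,
                                    fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "expressed genes",
                  fill = NULL,
                  title = "Partition of expressed genes after FNR correction") +
    ggplot2::theme_minimal()
}
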