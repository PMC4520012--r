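#' Genome and chromosome size constants
#'
#' Published size constants used by the density analysis: haploid genome
#' sizes of the two species (Gb), physical sizes of the X and Y
#' chromosomes (Mb), and the total physical span of the sequenced BAC
#' sets (Mb) per compartment.
#'
#' @return A list with elements `genome_gb` (named: latifolia, vulgaris),
#'   `chrom_mb` (named: X, Y) and `bac_span_mb` (named: X, Y, vulgaris).
#' @export
silene_sizes <- function() {
  list(
    genome_gb = c(latifolia = 2.7, vulgaris = 1.0),
    chrom_mb = c(X = 400, Y = 550),
    bac_span_mb = c(X = 1.7, Y = 1.09, vulgaris = 1.05)
  )
}

#' Gene density over a physical span
#'
#' @param n_genes Gene count (vectorised).
#' @param span_mb Physical span in Mb (> 0).
#' @param label Optional labels for the output rows.
#' @return Tibble with columns `label`, `n_genes`, `span_mb`, `density`
#'   (exact genes/Mb) and `density_rounded` (integer genes/Mb, half-up,
#'   the displayed convention).
#' @examples
#' gene_density(c(58, 17, 78), c(1.7, 1.09, 1.05), c("X", "Y", "vulgaris"))
#' @export
gene_density <- function(n_genes, span_mb, label = NA_character_) {
  check_that(
    "`n_genes` must be non-negative" = all(n_genes >= 0),
    "`span_mb` must be > 0" = all(span_mb > 0)
  )
  tibble(
    label = label, n_genes = n_genes, span_mb = span_mb,
    density = n_genes / span_mb,
    density_rounded = round_half_up(n_genes / span_mb)
  )
}

#' Ratio of two gene densities
#'
#' @param d_high Numerator density (the denser compartment).
#' @param d_low Denominator density (> 0).
#' @param decimals Decimal places kept (default 1, the displayed
#'   convention).
#' @return `d_high / d_low`, rounded half-up.
#' @examples
#' density_ratio(74, 34) # 2.2-fold denser outgroup
#' @export
density_ratio <- function(d_high, d_low, decimals = 1) {
  check_that("`d_low` must be > 0" = all(d_low > 0))
  round_half_up(d_high / d_low, decimals)
}

#' Expected density ratio from relative sizes
#'
#' Under the null of equal gene numbers, the density ratio between two
#' compartments is the inverse of their size ratio: a chromosome (or
#' genome) `size_big / size_small` times larger is expected to be that
#' many times less gene-dense.
#'
#' @param size_big,size_small Sizes in the same unit (> 0).
#' @param decimals Decimal places kept.
#' @return `size_big / size_small`, rounded half-up.
#' @examples
#' expected_ratio(550, 400) # Y/X size ratio, 1.4
#' expected_ratio(2.7, 1.0) # genome-size ratio, 2.7
#' @export
expected_ratio <- function(size_big, size_small, decimals = 1) {
  check_that("sizes must be > 0" = all(size_big > 0) && all(size_small > 0))
  round_half_up(size_big / size_small, decimals)
}

#' Y gene loss inferred from density shortfall
#'
#' If the Y is `size_ratio` times larger than the X purely through
#' accumulation of non-genic sequence, its expected gene density is
#' `d_x / size_ratio`. The shortfall of the observed Y density relative
#' to that expectation, `100 * (1 - d_y * size_ratio / d_x)`, estimates
#' the percentage of genes lost from the Y.
#'
#' @param d_y Observed Y density (genes/Mb).
#' @param d_x Observed X density (> 0).
#' @param size_ratio Y/X size ratio (>= 1).
#' @param rounded Round the result half-up to integer percent (default,
#'   the displayed convention); `FALSE` returns the exact percentage.
#' @return Loss percentage (0 when observation equals expectation).
#' @examples
#' loss_from_density(16, 34, 1.4) # 34 % loss
#' @export
loss_from_density <- function(d_y, d_x, size_ratio, rounded = TRUE) {
  check_that(
    "`d_x` must be > 0" = all(d_x > 0),
    "`size_ratio` must be >= 1" = all(size_ratio >= 1)
  )
  pct <- 100 * (1 - d_y * size_ratio / d_x)
  if (rounded) round_half_up(pct) else pct
}

#' Tandem-repeat span from read fraction
#'
#' Under uniform read coverage, the fraction of a clone's reads deriving
#' from a tandem repeat estimates the fraction of the insert the repeat
#' occupies, so its physical span is `read_fraction * insert_length_bp`.
#'
#' @param read_fraction Proportion of reads from the repeat, in `[0, 1]`.
#' @param insert_length_bp Clone insert length in bp (> 0).
#' @return Estimated repeat span in bp.
#' @export
repeat_span <- function(read_fraction, insert_length_bp) {
  check_that(
    "`read_fraction` must lie in [0, 1]" =
      all(read_fraction >= 0 & read_fraction <= 1),
    "`insert_length_bp` must be > 0" = all(insert_length_bp > 0)
  )
  read_fraction * insert_length_bp
}

#' Full density analysis of a gene table
#'
#' Computes per-compartment densities (X-linked, Y-linked, outgroup) from
#' a gene table and the BAC spans, the observed X-vs-outgroup and Y-vs-X
#' density ratios, the ratios expected from genome and chromosome sizes,
#' and the density-based Y gene-loss percentage.
#'
#' @param genes Validated gene table (all genes count, probes included:
#'   density is a property of the sequence, not of gene novelty).
#' @param sizes Size constants as from [silene_sizes()].
#' @return A list (class `density_report`) with elements `densities`
#'   (tibble), `ratios` (tibble of observed vs expected) and
#'   `loss_from_density_pct`.
#' @export
density_report <- function(genes, sizes = silene_sizes()) {
  genes <- validate_gene_table(genes)
  counts <- c(
    X = sum(genes$species == "latifolia" & genes$linkage == "X"),
    Y = sum(genes$species == "latifolia" & genes$linkage == "Y"),
    vulgaris = sum(genes$species == "vulgaris")
  )
  span <- sizes$bac_span_mb[names(counts)]
  dens <- gene_density(unname(counts), unname(span), names(counts))
  d <- stats::setNames(dens$density_rounded, dens$label)
  ratios <- tibble(
    comparison = c("vulgaris_vs_X", "X_vs_Y"),
    observed = c(density_ratio(d[["vulgaris"]], d[["X"]]),
                 density_ratio(d[["X"]], d[["Y"]])),
    expected = c(
      expected_ratio(sizes$genome_gb[["latifolia"]], sizes$genome_gb[["vulgaris"]]),
      expected_ratio(sizes$chrom_mb[["Y"]], sizes$chrom_mb[["X"]])
    )
  )
  structure(
    list(
      densities = dens,
      ratios = ratios,
      loss_from_density_pct = loss_from_density(
        d[["Y"]], d[["X"]],
        expected_ratio(sizes$chrom_mb[["Y"]], sizes$chrom_mb[["X"]]))
    ),
    class = "density_report"
  )
}

#' @export
print.density_report <- function(x, ...) {
  cat("Gene densities (genes/Mb):\n")
  print(x$densities)
  cat("\nDensity ratios (observed vs size-expected):\n")
  print(x$ratios)
  cat("\nDensity-based Y gene loss: ", x$loss_from_density_pct, " %\n", sep = "")
  invisible(x)
}
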