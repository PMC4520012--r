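#' BLAST hit filter criteria
#'
#' Bundle of thresholds applied per hit. With `strict = TRUE` (the
#' default) comparators are strict, exactly as the screening rules are
#' stated: e-value `<` `max_evalue`, identity `>` `min_identity`,
#' alignment length `>` `min_length` and, when `min_score` is given, bit
#' score `>` `min_score`. `strict = FALSE` switches every comparator to
#' its non-strict form for sensitivity analysis.
#'
#' @param max_evalue Largest acceptable e-value (exclusive when strict).
#' @param min_identity Percent-identity floor in `[0, 100]`.
#' @param min_length Alignment-length floor in bp.
#' @param min_score Optional bit-score floor; `NULL` disables the score
#'   criterion (the CDS-vs-contig rule set uses none).
#' @param strict Use strict (`<`, `>`) comparators.
#' @return An object of class `filter_criteria`.
#' @seealso [filter_preset()] for the two named rule sets.
#' @export
filter_criteria <- function(max_evalue, min_identity, min_length,
                            min_score = NULL, strict = TRUE) {
  check_that(
    "`max_evalue` must be > 0" = is.numeric(max_evalue) && max_evalue > 0,
    "`min_identity` must lie in [0, 100]" =
      is.numeric(min_identity) && min_identity >= 0 && min_identity <= 100,
    "`min_length` must be >= 0" = is.numeric(min_length) && min_length >= 0,
    "`min_score` must be numeric or NULL" =
      is.null(min_score) || is.numeric(min_score)
  )
  structure(
    list(max_evalue = max_evalue, min_identity = min_identity,
         min_length = min_length, min_score = min_score,
         strict = isTRUE(strict)),
    class = "filter_criteria"
  )
}

#' @export
print.filter_criteria <- function(x, ...) {
  cmp <- if (x$strict) c("<", ">") else c("<=", ">=")
  cat("<filter_criteria> e-value ", cmp[1], " ", format(x$max_evalue),
      ", identity ", cmp[2], " ", x$min_identity,
      " %, length ", cmp[2], " ", x$min_length, " bp",
      if (!is.null(x$min_score)) paste0(", score ", cmp[2], " ", x$min_score),
      "\n", sep = "")
  invisible(x)
}

#' Named filter presets
#'
#' Two rule sets are used in the pipeline: `"cds_vs_contigs"` for matching
#' BAC coding sequences to RNA-seq contigs (e-value < 1e-5, identity
#' > 90 %, length > 50 bp) and `"male_specific"`, the stricter screen for
#' diverged Y copies among male-specific contigs (length > 100 bp,
#' e-value < 1e-4, bit score > 80, identity > 80 %).
#'
#' @param preset `"cds_vs_contigs"` or `"male_specific"`.
#' @param strict Use strict comparators (default).
#' @return A [filter_criteria()] object.
#' @export
filter_preset <- function(preset = c("cds_vs_contigs", "male_specific"),
                          strict = TRUE) {
  preset <- match.arg(preset)
  switch(preset,
    cds_vs_contigs = filter_criteria(1e-5, 90, 50, NULL, strict),
    male_specific  = filter_criteria(1e-4, 80, 100, 80, strict)
  )
}

#' Filter BLAST hits by threshold criteria
#'
#' Keeps exactly the hits satisfying every criterion, in input order.
#' Multiple retained subjects per query are allowed (one BAC CDS may match
#' several RNA-seq contigs because of assembly fragmentation).
#'
#' @param hits A tibble of hits as from [read_blast_table()] (columns
#'   `evalue`, `pct_identity`, `aln_length` and, if a score criterion is
#'   set, `score`).
#' @param criteria A [filter_criteria()] object.
#' @return The retained rows of `hits`.
#' @examples
#' hits <- tibble::tibble(query_id = "g1", subject_id = "c1",
#'                        pct_identity = 95, aln_length = 120,
#'                        evalue = 1e-30, score = 200)
#' filter_hits(hits, filter_preset("cds_vs_contigs"))
#' @export
filter_hits <- function(hits, criteria) {
  check_that(
    "`criteria` must be a filter_criteria object" =
      inherits(criteria, "filter_criteria"),
    "`hits` must have columns evalue, pct_identity, aln_length" =
      all(c("evalue", "pct_identity", "aln_length") %in% names(hits))
  )
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) return(hits)
  lt <- if (criteria$strict) `<` else `<=`
  gt <- if (criteria$strict) `>` else `>=`
  keep <- lt(hits$evalue, criteria$max_evalue) &
    gt(hits$pct_identity, criteria$min_identity) &
    gt(hits$aln_length, criteria$min_length)
  if (!is.null(criteria$min_score)) {
    check_that("`hits` must have a score column for this rule set" =
                 "score" %in% names(hits))
    keep <- keep & gt(hits$score, criteria$min_score)
  }
  hits[keep, , drop = FALSE]
}

#' Identify male-specific contigs
#'
#' A contig is male-specific when it has reads in every male library and
#' none in any female library. The `te_free_min_reads` variant
#' additionally drops contigs matching transposable-element sequence and
#' contigs whose best library has no more than `min_reads` reads (a noisy
#' expression floor).
#'
#' @param counts Long tibble with columns `contig_id`, `library_id`,
#'   `sex` (`"male"`/`"female"`) and `count` (non-negative reads).
#'   Missing contig x library combinations count as zero reads.
#' @param variant `"all"` or `"te_free_min_reads"`.
#' @param te_matches Character vector of contig ids with TE matches
#'   (used by the `te_free_min_reads` variant).
#' @param min_reads Read floor: keep only contigs with `count > min_reads`
#'   in at least one library (default 10).
#' @return A tibble with column `contig_id` (the retained set, sorted).
#' @export
male_specific_contigs <- function(counts,
                                  variant = c("all", "te_free_min_reads"),
                                  te_matches = character(),
                                  min_reads = 10) {
  variant <- match.arg(variant)
  check_that(
    "`counts` needs columns contig_id, library_id, sex, count" =
      all(c("contig_id", "library_id", "sex", "count") %in% names(counts)),
    "`counts` must be non-empty" = nrow(counts) > 0,
    "read counts must be non-negative" = all(counts$count >= 0),
    "sex must be male or female" = all(counts$sex %in% c("male", "female"))
  )
  libs <- distinct(as_tibble(counts), .data$library_id, .data$sex)
  if (anyDuplicated(libs$library_id) > 0) {
    abort("a library_id is labelled with more than one sex")
  }
  if (!all(c("male", "female") %in% libs$sex)) {
    abort("both male and female libraries are required")
  }
  # complete grid: absent combinations are zero counts
  grid <- tidyr::expand_grid(contig_id = unique(counts$contig_id),
                             library_id = libs$library_id) %>%
    left_join(counts[c("contig_id", "library_id", "count")],
              by = c("contig_id", "library_id")) %>%
    mutate(count = dplyr::coalesce(.data$count, 0)) %>%
    left_join(libs, by = "library_id")
  per <- grid %>%
    group_by(.data$contig_id) %>%
    summarise(
      all_male = all(.data$count[.data$sex == "male"] > 0),
      any_female = any(.data$count[.data$sex == "female"] > 0),
      max_count = max(.data$count),
      .groups = "drop"
    ) %>%
    filter(.data$all_male, !.data$any_female)
  if (variant == "te_free_min_reads") {
    per <- per %>%
      filter(!(.data$contig_id %in% te_matches),
             .data$max_count > min_reads)
  }
  per %>% select("contig_id") %>% arrange(.data$contig_id)
}

#' Screen undetected genes against male-specific contigs
#'
#' Among candidate genes not ascertained as sex-linked, flags those with
#' at least one hit to a male-specific contig surviving the stringent
#' rule set — such genes may be X/Y pairs whose diverged Y copy assembled
#' into a separate (male-specific) contig rather than true hemizygotes.
#'
#' @param hits Hit tibble (queries are candidate genes, subjects are
#'   male-specific contigs).
#' @param candidates Character vector of candidate gene ids.
#' @param criteria Rule set to apply; defaults to the stringent
#'   `male_specific` preset.
#' @return A tibble with columns `gene_id` and `n_hits` (surviving hits),
#'   one row per flagged candidate.
#' @export
screen_hemizygous_candidates <- function(hits, candidates,
                                         criteria = filter_preset("male_specific")) {
  kept <- filter_hits(hits, criteria)
  kept %>%
    filter(.data$query_id %in% candidates) %>%
    count(gene_id = .data$query_id, name = "n_hits") %>%
    arrange(.data$gene_id)
}
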