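#' Combine per-study contig calls into per-gene categories
#'
#' Each BAC-located gene may match several RNA-seq contigs across several
#' studies. The per-gene category merges the matching contigs' labels
#' with the precedence `XY > X_HEMI > UNDETECTED`:
#'
#' * `XY` if any matching contig is classified X/Y in any study;
#' * `X_HEMI` if at least one matching contig is classified X-hemizygous
#'   and no matching contig is classified X/Y;
#' * `UNDETECTED` if all matching contigs failed to be detected as
#'   sex-linked.
#'
#' Genes appear in the output only if they have matches; see
#' [classify_genes()] for the full per-gene table including `NO_MATCH`.
#' Matches whose `(study_id, contig_id)` is absent from `calls` are
#' treated as `NOT_SEX_LINKED` with a warning (the three studies'
#' contig catalogues are heterogeneous).
#'
#' @param matches Tibble of surviving matches with columns `gene_id`,
#'   `study_id`, `contig_id`; duplicates are ignored.
#' @param calls Tibble of per-study contig calls (`study_id`,
#'   `contig_id`, `label`), as from [read_contig_calls()].
#' @return Tibble with columns `gene_id`, `expressed` (always `TRUE`
#'   here) and `category`; one row per gene with at least one match. The
#'   result is invariant under permutation and duplication of matches.
#' @export
combine_calls <- function(matches, calls) {
  check_that(
    "`matches` needs columns gene_id, study_id, contig_id" =
      all(c("gene_id", "study_id", "contig_id") %in% names(matches)),
    "`calls` needs columns study_id, contig_id, label" =
      all(c("study_id", "contig_id", "label") %in% names(calls)),
    "labels must be XY, X_HEMI or NOT_SEX_LINKED" =
      all(calls$label %in% call_levels)
  )
  matches <- distinct(as_tibble(matches),
                      .data$gene_id, .data$study_id, .data$contig_id)
  if (nrow(matches) == 0) {
    return(tibble(gene_id = character(), expressed = logical(),
                  category = character()))
  }
  joined <- left_join(matches, as_tibble(calls),
                      by = c("study_id", "contig_id"))
  n_orphan <- sum(is.na(joined$label))
  if (n_orphan > 0) {
    warn(sprintf(
      "%d match(es) reference contigs absent from the call table; treated as NOT_SEX_LINKED",
      n_orphan))
    joined$label[is.na(joined$label)] <- "NOT_SEX_LINKED"
  }
  joined %>%
    group_by(.data$gene_id) %>%
    summarise(
      expressed = TRUE,
      category = if (any(.data$label == "XY")) "XY"
                 else if (any(.data$label == "X_HEMI")) "X_HEMI"
                 else "UNDETECTED",
      .groups = "drop"
    )
}

#' Classify every BAC-located gene against the combined RNA-seq calls
#'
#' Applies [combine_calls()] and completes the table with one `NO_MATCH`
#' row (`expressed = FALSE`) for every gene in `genes` without a single
#' surviving match. Genes of the outgroup species are skipped (they have
#' no sex-linkage category). A Y-linked gene whose combined category is
#' `X_HEMI` is biologically contradictory and is flagged `anomalous`;
#' whether to drop it is the loss estimator's decision, not the
#' classifier's.
#'
#' @inheritParams combine_calls
#' @param genes Validated gene table (see [validate_gene_table()]).
#' @return Tibble with columns `gene_id`, `expressed`, `category`,
#'   `anomalous`, one row per focal-species gene.
#' @export
classify_genes <- function(genes, matches, calls) {
  genes <- validate_gene_table(genes)
  focal <- filter(genes, .data$species == "latifolia")
  extraneous <- setdiff(unique(matches$gene_id), genes$gene_id)
  if (length(extraneous) > 0) {
    abort(paste0("matches reference unknown gene_id: ", extraneous[1]),
          class = "ydegen_validation_error")
  }
  combined <- combine_calls(
    filter(matches, .data$gene_id %in% focal$gene_id), calls)
  focal %>%
    select("gene_id", "linkage") %>%
    left_join(combined, by = "gene_id") %>%
    mutate(
      expressed = !is.na(.data$category),
      category = if_else(is.na(.data$category), "NO_MATCH", .data$category),
      anomalous = .data$linkage == "Y" & .data$category == "X_HEMI"
    ) %>%
    select("gene_id", "expressed", "category", "anomalous")
}

#' Tabulate per-linkage category counts
#'
#' Counts genes by linkage (X or Y) and combined category, the layout of
#' the gene-loss bookkeeping table: total genes, genes without RNA-seq
#' matches, genes retained for analysis (expressed), and the three
#' expressed categories (X/Y pair detected, X-hemizygous detected, not
#' ascertained as sex-linked).
#'
#' @param combined Per-gene classification from [classify_genes()].
#' @param genes Validated gene table.
#' @param probes Which genes to count: `"exclude"` (new genes only, the
#'   loss-analysis set), `"single_copy"` (new genes plus probe genes
#'   lacking one of the two sex-linked copies, the BAC-vs-RNA-seq
#'   comparison set) or `"include"` (all focal-species genes).
#' @return Tibble with one row per linkage (`X`, `Y`) and columns
#'   `n_total`, `n_no_match`, `n_retained`, `n_xy`, `n_hemi`,
#'   `n_undetected`, `n_anomalous_hemi`. Per row,
#'   `n_xy + n_hemi + n_undetected = n_retained` and
#'   `n_retained + n_no_match = n_total`.
#' @export
tabulate_categories <- function(combined, genes,
                                probes = c("exclude", "single_copy", "include")) {
  probes <- match.arg(probes)
  genes <- validate_gene_table(genes)
  focal <- filter(genes, .data$species == "latifolia")
  if (!all(combined$gene_id %in% focal$gene_id)) {
    abort("combined calls reference gene ids absent from the gene table",
          class = "ydegen_validation_error")
  }
  keep <- switch(probes,
    exclude = filter(focal, !.data$is_probe),
    include = focal,
    single_copy = {
      fam <- focal %>%
        filter(.data$is_probe) %>%
        group_by(.data$probe_family) %>%
        filter(dplyr::n() == 1) %>%
        ungroup()
      bind_rows(filter(focal, !.data$is_probe), fam)
    }
  )
  tab <- keep %>%
    select("gene_id", "linkage") %>%
    left_join(combined, by = "gene_id")
  if (anyNA(tab$category)) {
    abort("every gene must have a combined call; run classify_genes() first",
          class = "ydegen_validation_error")
  }
  tab %>%
    group_by(linkage = .data$linkage) %>%
    summarise(
      n_total = n(),
      n_no_match = sum(.data$category == "NO_MATCH"),
      n_retained = sum(.data$category != "NO_MATCH"),
      n_xy = sum(.data$category == "XY"),
      n_hemi = sum(.data$category == "X_HEMI"),
      n_undetected = sum(.data$category == "UNDETECTED"),
      n_anomalous_hemi = sum(.data$category == "X_HEMI" & .data$anomalous),
      .groups = "drop"
    ) %>%
    arrange(.data$linkage)
}
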