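#' Read a 12-column tabular BLAST hit table
#'
#' Reads the standard 12-column tab-separated BLAST output dialect
#' (query, subject, percent identity, alignment length, mismatches, gap
#' opens, query start/end, subject start/end, e-value, bit score). The file
#' has no header row. The bit score column is the only score the format
#' carries, so downstream score thresholds apply to it.
#'
#' @param path Path to a tab-separated hit table.
#' @param dialect Only `"tabular12"` is supported.
#' @return A tibble with one row per hit and columns `query_id`,
#'   `subject_id`, `pct_identity`, `aln_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `score`.
#' @details Malformed rows (wrong column count, non-numeric identity,
#'   length or e-value) raise an error naming the offending line number;
#'   well-formed rows are never silently dropped.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines("g1\tc1\t95.0\t120\t5\t0\t1\t120\t1\t120\t1e-30\t200", f)
#' read_blast_table(f)
#' @export
read_blast_table <- function(path, dialect = "tabular12") {
  check_that(
    "`dialect` must be \"tabular12\"" = identical(dialect, "tabular12"),
    "`path` must be an existing file" = is.character(path) && file.exists(path)
  )
  cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "evalue", "score")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- tibble(query_id = character(), subject_id = character(),
                  pct_identity = double(), aln_length = integer(),
                  mismatches = integer(), gap_opens = integer(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  evalue = double(), score = double())
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    abort(sprintf("malformed BLAST row at line %d: expected 12 columns, found %d",
                  which(nf != 12)[1], nf[nf != 12][1]),
          class = "ydegen_parse_error")
  }
  mat <- do.call(rbind, fields)
  num <- function(j, what, integer = FALSE) {
    v <- suppressWarnings(as.numeric(mat[, j]))
    if (anyNA(v)) {
      abort(sprintf("malformed BLAST row at line %d: non-numeric %s (%s)",
                    which(is.na(v))[1], what, mat[which(is.na(v))[1], j]),
            class = "ydegen_parse_error")
    }
    if (integer) as.integer(v) else v
  }
  out <- tibble(
    query_id = mat[, 1], subject_id = mat[, 2],
    pct_identity = num(3, "% identity"),
    aln_length = num(4, "alignment length", integer = TRUE),
    mismatches = num(5, "mismatch count", integer = TRUE),
    gap_opens = num(6, "gap-open count", integer = TRUE),
    q_start = num(7, "query start", integer = TRUE),
    q_end = num(8, "query end", integer = TRUE),
    s_start = num(9, "subject start", integer = TRUE),
    s_end = num(10, "subject end", integer = TRUE),
    evalue = num(11, "e-value"),
    score = num(12, "bit score")
  )
  check_that(
    "alignment lengths must be >= 1" = all(out$aln_length >= 1),
    "% identity must lie in [0, 100]" =
      all(out$pct_identity >= 0 & out$pct_identity <= 100),
    "e-values must be non-negative" = all(out$evalue >= 0)
  )
  out
}

#' Validate a gene table
#'
#' Checks the per-gene invariants: unique ids, known species and linkage
#' levels, no sex linkage assigned to the outgroup species (which has no
#' sex chromosomes), probe/new mutually exclusive, non-negative RPKM.
#' Missing optional columns (`is_new`, `has_outgroup_homolog`, `rpkm`,
#' `probe_family`) are added with neutral defaults.
#'
#' @param genes A data frame of gene records.
#' @return The validated tibble (invisibly the same data, with optional
#'   columns filled in).
#' @export
validate_gene_table <- function(genes) {
  genes <- as_tibble(genes)
  required <- c("gene_id", "species", "linkage", "is_probe", "bac_id")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0) {
    abort(paste0("gene table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "ydegen_validation_error")
  }
  if (!"is_new" %in% names(genes)) genes$is_new <- !genes$is_probe
  if (!"has_outgroup_homolog" %in% names(genes)) {
    genes$has_outgroup_homolog <- NA
  }
  if (!"rpkm" %in% names(genes)) genes$rpkm <- NA_real_
  if (!"probe_family" %in% names(genes)) genes$probe_family <- NA_character_
  # header-only files give type guesses no data can correct
  genes <- mutate(genes,
                  across(c("is_probe", "is_new", "has_outgroup_homolog"),
                         as.logical),
                  rpkm = as.numeric(.data$rpkm),
                  probe_family = as.character(.data$probe_family))
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene_id: ", dup[1]),
          class = "ydegen_validation_error")
  }
  check_that(
    "species must be latifolia or vulgaris" =
      all(genes$species %in% c("latifolia", "vulgaris")),
    "linkage must be X, Y or unknown" = all(genes$linkage %in% linkage_levels),
    "rpkm must be non-negative where present" =
      all(is.na(genes$rpkm) | genes$rpkm >= 0),
    "is_probe and is_new are mutually exclusive" =
      !any(genes$is_probe & genes$is_new),
    class = "ydegen_validation_error"
  )
  bad <- genes$species == "vulgaris" & genes$linkage != "unknown"
  if (any(bad)) {
    abort(sprintf(
      "gene %s: the outgroup species has no sex chromosomes, linkage must be \"unknown\"",
      genes$gene_id[bad][1]), class = "ydegen_validation_error")
  }
  genes
}

#' Read a gene table
#'
#' Reads a tab-separated, headered table of BAC-located gene records and
#' validates it with [validate_gene_table()]. Required columns:
#' `gene_id`, `species` (latifolia/vulgaris), `linkage` (X/Y/unknown),
#' `is_probe`, `bac_id`; optional: `is_new`, `has_outgroup_homolog`,
#' `rpkm`, `probe_family`.
#'
#' @param path Path to a TSV file with a header row.
#' @return A validated tibble of gene records.
#' @export
read_gene_table <- function(path) {
  check_that("`path` must be an existing file" =
               is.character(path) && file.exists(path))
  genes <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", species = "c", linkage = "c", bac_id = "c",
    is_probe = "l", .default = readr::col_guess()
  ), progress = FALSE)
  if ("rpkm" %in% names(genes)) genes$rpkm <- as.numeric(genes$rpkm)
  validate_gene_table(genes)
}

#' Read a per-study contig sex-linkage call table
#'
#' @param path Path to a TSV with header columns `study_id`, `contig_id`,
#'   `label` (one of `XY`, `X_HEMI`, `NOT_SEX_LINKED`).
#' @return A tibble of calls; `(study_id, contig_id)` pairs are unique.
#' @export
read_contig_calls <- function(path) {
  check_that("`path` must be an existing file" =
               is.character(path) && file.exists(path))
  calls <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  check_that(
    "contig-call table needs columns study_id, contig_id, label" =
      all(c("study_id", "contig_id", "label") %in% names(calls)),
    "label must be XY, X_HEMI or NOT_SEX_LINKED" =
      all(calls$label %in% call_levels),
    class = "ydegen_validation_error"
  )
  if (anyDuplicated(calls[c("study_id", "contig_id")]) > 0) {
    abort("duplicate (study_id, contig_id) in contig-call table",
          class = "ydegen_validation_error")
  }
  as_tibble(calls)
}

#' Read a tester-gene table
#'
#' Tester genes are previously validated X/Y gene pairs used to estimate
#' the RNA-seq false-negative rate. `detected_sexlinked` implies
#' `expressed` (a gene cannot be ascertained sex-linked without matching a
#' contig).
#'
#' @param path Path to a TSV with header columns `gene_id`, `expressed`,
#'   `detected_sexlinked` and optionally `provenance`.
#' @return A tibble of tester records.
#' @export
read_tester_table <- function(path) {
  check_that("`path` must be an existing file" =
               is.character(path) && file.exists(path))
  testers <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", expressed = "l", detected_sexlinked = "l",
    .default = "c"
  ), progress = FALSE)
  check_that(
    "tester table needs columns gene_id, expressed, detected_sexlinked" =
      all(c("gene_id", "expressed", "detected_sexlinked") %in% names(testers)),
    "detected_sexlinked implies expressed" =
      all(testers$expressed | !testers$detected_sexlinked),
    class = "ydegen_validation_error"
  )
  as_tibble(testers)
}

#' Write and read a pipeline report bundle
#'
#' A report bundle collects every table the pipeline produces (density
#' summary, category tabulation, loss estimates, test results) in one
#' structure serialisable to JSON. `read_report(write_report(x, f))`
#' restores an equivalent bundle; absent components are recorded as absent
#' rather than dropped.
#'
#' @param bundle A list of data frames / scalars (class `ydegen_report`).
#' @param path Output (input) JSON path.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns the bundle with tabular components restored as tibbles.
#' @export
write_report <- function(bundle, path) {
  check_that("`bundle` must be a named list" =
               is.list(bundle) && !is.null(names(bundle)))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(sprintf("cannot write report: directory %s does not exist", dir))
  }
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  check_that("`path` must be an existing file" =
               is.character(path) && file.exists(path))
  bundle <- jsonlite::read_json(path, simplifyVector = TRUE)
  bundle <- lapply(bundle, function(x) if (is.data.frame(x)) as_tibble(x) else x)
  class(bundle) <- c("ydegen_report", "list")
  bundle
}
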