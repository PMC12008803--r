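#' @importFrom rlang .data abort inform warn %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# Controlled vocabularies ------------------------------------------------

#' Consequence classes recognised by the pipeline
#'
#' Variant consequence annotations are treated as a fixed vocabulary supplied
#' with the library design (they are curated upstream, never computed from
#' HGVS strings, which the pipeline treats as opaque identifiers).
#'
#' @return Character vector of valid consequence labels.
#' @export
consequence_levels <- function() {
  c("synonymous", "missense", "nonsense", "canonical_splice", "splice_region",
    "intronic", "utr5", "utr3", "upstream", "start_loss", "mnv", "deletion",
    "insertion")
}

clinvar_levels <- function() {
  c("pathogenic_or_likely", "benign_or_likely", "vus", "none")
}

sample_roles <- function() c("pre", "post", "negative_control", "other")

.dna_ok <- function(x) grepl("^[ACGTN]+$", x)

# Screen configuration ---------------------------------------------------

#' Screen analysis configuration
#'
#' Bundles every tunable threshold of the analysis. Defaults correspond to a
#' negative-selection essentiality screen scored from a single condition:
#' pegRNAs need at least 10 surrogate-target (ST) reads before an editing
#' percentage is reported, pegRNAs with more than 5% apparent editing in the
#' negative-control sample are discarded as background, cassette elements may
#' diverge from their design by at most 10% substitutions, and scoring keeps
#' pegRNAs with pre-selection frequency >= 6e-5 and ST editing >= 75%.
#'
#' @param min_st_reads Minimum ST read count before an editing percentage is
#'   defined (reads below this leave `st_editing_pct` as `NA`).
#' @param neg_ctrl_editing_max_pct pegRNAs whose negative-control editing
#'   strictly exceeds this percentage are excluded as background artefacts.
#' @param element_mismatch_frac Maximum substitution fraction tolerated when
#'   matching a cassette element against its design (allowance is
#'   `floor(frac * length)`).
#' @param freq_min Minimum pre-selection pegRNA frequency retained for scoring.
#' @param st_activity_min_pct Minimum pre-selection ST editing percentage
#'   retained for scoring.
#' @param q_cutoff BH-adjusted q-value below which (strictly) a variant is
#'   called loss-of-function.
#' @param selection_direction `"depletion"` for negative selection (LoF drops
#'   out) or `"enrichment"` for positive selection (LoF enriches, e.g. 6TG).
#' @param neutral_consequences Consequence classes forming the neutral
#'   (normalisation and null-model) set.
#' @param plof_consequences Consequence classes forming the putative-LoF
#'   benchmark set.
#' @param et_ctrl_freq_max Endogenous-target variants whose negative-control
#'   frequency exceeds this are excluded (site-specific sequencing error).
#' @param et_min_log2_gain Minimum log2 frequency gain across the editing
#'   window for an endogenous-target variant to be considered installed.
#' @param high_stringency_mean_st_pct Mean per-variant ST editing threshold
#'   used for high-stringency re-analysis.
#' @param min_neutral Minimum number of neutral entries required for any
#'   median normalisation or null fit.
#' @param scoring_mode `"single"` (normalise pegRNA scores, then average per
#'   variant) or `"multi"` (per-condition function scores, normalised,
#'   averaged across >= 2 conditions, re-normalised).
#' @param st_anchor_len Length of the invariant ST 3' end used for cassette
#'   cross-checking, so edited STs are not discarded.
#' @param one_sided Use one-sided p-values in the selection direction
#'   (default); `FALSE` gives two-sided tests.
#'
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(min_st_reads = 10,
                          neg_ctrl_editing_max_pct = 5,
                          element_mismatch_frac = 0.10,
                          freq_min = 6e-5,
                          st_activity_min_pct = 75,
                          q_cutoff = 0.05,
                          selection_direction = c("depletion", "enrichment"),
                          neutral_consequences = "synonymous",
                          plof_consequences = c("nonsense", "canonical_splice"),
                          et_ctrl_freq_max = 4e-4,
                          et_min_log2_gain = 1.0,
                          high_stringency_mean_st_pct = 36,
                          min_neutral = 5,
                          scoring_mode = c("single", "multi"),
                          st_anchor_len = 15,
                          one_sided = TRUE) {
  selection_direction <- match.arg(selection_direction)
  scoring_mode <- match.arg(scoring_mode)
  stopifnot(
    min_st_reads >= 1,
    neg_ctrl_editing_max_pct >= 0, neg_ctrl_editing_max_pct <= 100,
    element_mismatch_frac >= 0, element_mismatch_frac < 1,
    freq_min >= 0, freq_min < 1,
    st_activity_min_pct >= 0, st_activity_min_pct <= 100,
    q_cutoff > 0, q_cutoff < 1,
    et_ctrl_freq_max > 0, et_min_log2_gain >= 0,
    min_neutral >= 2, st_anchor_len >= 5
  )
  bad <- setdiff(neutral_consequences, consequence_levels())
  if (length(bad) > 0) {
    abort(paste0("Unknown neutral consequence(s): ", toString(bad)))
  }
  structure(
    list(
      min_st_reads = as.integer(min_st_reads),
      neg_ctrl_editing_max_pct = neg_ctrl_editing_max_pct,
      element_mismatch_frac = element_mismatch_frac,
      freq_min = freq_min,
      st_activity_min_pct = st_activity_min_pct,
      q_cutoff = q_cutoff,
      selection_direction = selection_direction,
      neutral_consequences = neutral_consequences,
      plof_consequences = plof_consequences,
      et_ctrl_freq_max = et_ctrl_freq_max,
      et_min_log2_gain = et_min_log2_gain,
      high_stringency_mean_st_pct = high_stringency_mean_st_pct,
      min_neutral = as.integer(min_neutral),
      scoring_mode = scoring_mode,
      st_anchor_len = as.integer(st_anchor_len),
      one_sided = isTRUE(one_sided)
    ),
    class = "screen_config"
  )
}

#' Read a screen configuration from a YAML file
#'
#' Keys mirror the arguments of [screen_config()]; absent keys keep their
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `screen_config` list.
#' @export
read_screen_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Reading YAML configs requires the 'yaml' package.")
  }
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(screen_config)))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", toString(unknown)))
  }
  do.call(screen_config, vals)
}

# Library reading --------------------------------------------------------

library_design_cols <- function() {
  c("pegrna_id", "variant_id", "spacer", "scaffold", "extension",
    "st_ref", "st_edit_core", "pegrna_bc", "library_bc")
}

feature_cols <- function() {
  c("pbs_length", "rtt_length", "rtt_homology_length",
    "nick_to_edit_distance", "pbs_gc_fraction", "spacer_ontarget_score")
}

variant_cols <- function() {
  c("variant_id", "gene", "genomic_pos", "consequence")
}

#' Read and validate a pegRNA-ST library design table
#'
#' The library TSV carries one row per pegRNA: all cassette element sequences
#' (spacer, scaffold, 3' extension, 55-nt surrogate target, the intended edit
#' core with exactly 5 nt of flank on each side, 16-nt pegRNA barcode, 10-nt
#' library barcode), the encoded variant with its curated consequence class,
#' and optional numeric design features. Sequences are validated against the
#' schema (DNA alphabet, 55-nt ST, unique pegRNA ids and barcodes, edit core
#' genuinely different from the reference window).
#'
#' @param path Path to a tab-separated library table. Lines starting with `#`
#'   are comments.
#' @param neutral_consequences,plof_consequences Consequence classes defining
#'   the neutral and putative-LoF variant sets; ignored if the table already
#'   has logical `neutral_set` / `plof_set` columns.
#' @return A list of class `pe_library` with tibbles `designs` and `variants`.
#' @export
read_library <- function(path,
                         neutral_consequences = "synonymous",
                         plof_consequences = c("nonsense", "canonical_splice")) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(raw) == 0) abort("Library table is empty.")
  validate_library_table(raw)
  designs <- raw |>
    select(any_of(c(library_design_cols(), feature_cols()))) |>
    as_tibble()
  variants <- raw |>
    select(any_of(c(variant_cols(), "clinvar", "neutral_set", "plof_set"))) |>
    distinct()
  if (anyDuplicated(variants$variant_id) > 0) {
    abort("Variants with inconsistent annotation across library rows.")
  }
  if (!"clinvar" %in% names(variants)) variants$clinvar <- "none"
  if (!"neutral_set" %in% names(variants)) {
    variants$neutral_set <- variants$consequence %in% neutral_consequences
  }
  if (!"plof_set" %in% names(variants)) {
    variants$plof_set <- variants$consequence %in% plof_consequences
  }
  if (any(variants$neutral_set & variants$plof_set)) {
    abort("A variant cannot be in both the neutral and the pLoF set.")
  }
  new_pe_library(designs, variants)
}

new_pe_library <- function(designs, variants) {
  structure(list(designs = as_tibble(designs), variants = as_tibble(variants)),
            class = "pe_library")
}

#' @export
print.pe_library <- function(x, ...) {
  cat("<pe_library> ", nrow(x$designs), " pegRNAs programming ",
      nrow(x$variants), " variants\n", sep = "")
  cat("  neutral set: ", sum(x$variants$neutral_set),
      ", pLoF set: ", sum(x$variants$plof_set), "\n", sep = "")
  invisible(x)
}

validate_library_table <- function(tab) {
  missing <- setdiff(c(library_design_cols(), variant_cols()), names(tab))
  if (length(missing) > 0) {
    abort(paste0("Library table lacks column(s): ", toString(missing)))
  }
  if (anyDuplicated(tab$pegrna_id) > 0) {
    dup <- unique(tab$pegrna_id[duplicated(tab$pegrna_id)])
    abort(paste0("Duplicate pegrna_id: ", toString(utils::head(dup, 3))))
  }
  seq_cols <- c("spacer", "scaffold", "extension", "st_ref", "st_edit_core",
                "pegrna_bc", "library_bc")
  for (col in seq_cols) {
    x <- tab[[col]]
    if (any(is.na(x)) || any(!nzchar(x))) {
      abort(paste0("Empty sequence in column '", col, "'."))
    }
    if (any(!.dna_ok(x))) {
      abort(paste0("Non-DNA characters in column '", col, "'."))
    }
  }
  if (any(nchar(tab$st_ref) != 55L)) {
    abort("st_ref must be exactly 55 nt (surrogate target length).")
  }
  if (any(nchar(tab$pegrna_bc) != 16L)) abort("pegrna_bc must be 16 nt.")
  if (any(nchar(tab$library_bc) != 10L)) abort("library_bc must be 10 nt.")
  if (anyDuplicated(tab$pegrna_bc) > 0) {
    abort("pegRNA barcodes must be unique within the library.")
  }
  # edit core = intended edit plus exactly 5 nt flank each side
  if (any(nchar(tab$st_edit_core) < 11L)) {
    abort("st_edit_core must be at least 11 nt (>=1 nt edit + 2x5 nt flank).")
  }
  if (any(nchar(tab$st_edit_core) > nchar(tab$st_ref))) {
    abort("st_edit_core longer than the surrogate target.")
  }
  hit <- mapply(grepl, tab$st_edit_core, tab$st_ref,
                MoreArgs = list(fixed = TRUE))
  if (any(hit)) {
    abort("st_edit_core must differ from the unedited surrogate target.")
  }
  bad_cons <- setdiff(unique(tab$consequence), consequence_levels())
  if (length(bad_cons) > 0) {
    abort(paste0("Unknown consequence class(es): ", toString(bad_cons)))
  }
  invisible(tab)
}

# Sample sheet -----------------------------------------------------------

#' Read and validate a sample sheet
#'
#' One row per sequencing sample: screen, condition (cell line and whether
#' co-selection was applied), timepoint (numeric, e.g. day), replicate and
#' role. Every screen must provide at least one pre-selection and one
#' post-selection sample and exactly one negative-control sample group (cells
#' carrying the library but no prime editor, harvested at the earliest
#' timepoint, which define background editing).
#'
#' @param path Path to a tab-separated sample sheet.
#' @return A tibble with one row per sample and a derived `condition` column
#'   (`cell_line` crossed with co-selection status).
#' @export
read_sample_sheet <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(tab) == 0) abort("Sample sheet is empty.")
  required <- c("sample_id", "cell_line", "coselection", "timepoint",
                "replicate", "role", "screen_id")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0("Sample sheet lacks column(s): ", toString(missing)))
  }
  validate_samples(as_tibble(tab))
}

validate_samples <- function(tab) {
  bad_role <- setdiff(unique(tab$role), sample_roles())
  if (length(bad_role) > 0) {
    abort(paste0("Unknown sample role(s): ", toString(bad_role)))
  }
  if (anyDuplicated(tab$sample_id) > 0) abort("Duplicate sample_id.")
  tab$coselection <- as.logical(tab$coselection)
  tab$timepoint <- as.numeric(tab$timepoint)
  by_screen <- split(tab, tab$screen_id)
  for (scr in by_screen) {
    id <- scr$screen_id[1]
    if (!any(scr$role == "pre")) {
      abort(paste0("Screen '", id, "' has no pre-selection sample."))
    }
    if (!any(scr$role == "post")) {
      abort(paste0("Screen '", id, "' has no post-selection sample."))
    }
    nc <- scr[scr$role == "negative_control", ]
    if (nrow(nc) == 0) {
      abort(paste0("Screen '", id, "' has no negative-control sample."))
    }
    if (length(unique(nc$timepoint)) > 1) {
      abort(paste0("Screen '", id,
                   "' has negative controls at multiple timepoints; ",
                   "exactly one control group is expected."))
    }
  }
  mutate(tab, condition = sample_condition(.data$cell_line, .data$coselection))
}

#' Condition label for a sample
#'
#' A condition is a cell line crossed with co-selection status; replicates and
#' timepoints within a condition are collapsed during scoring.
#'
#' @param cell_line Character vector.
#' @param coselection Logical vector.
#' @return Character vector of condition labels.
#' @export
sample_condition <- function(cell_line, coselection) {
  paste0(cell_line, ifelse(coselection, "+cosel", "-cosel"))
}

# Table round-trip -------------------------------------------------------

#' Write a result table to TSV
#'
#' All pipeline outputs are plain TSV so any stage can be re-run standalone.
#' `NA` encodes undefined values; the reader tolerates `#` comment lines.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a result table written by [write_screen_table()]
#'
#' @param path Path to a TSV file.
#' @return A tibble. Column types are inferred; `NA` restores undefined
#'   values.
#' @export
read_screen_table <- function(path) {
  readr::read_tsv(path, comment = "#", na = "NA", show_col_types = FALSE,
                  progress = FALSE)
}

# FASTQ ------------------------------------------------------------------

#' Read a (possibly gzipped) FASTQ file as a character vector of sequences
#'
#' Qualities are ignored throughout the cassette pipeline: the published
#' processing applies no base-quality filtering to cassette reads.
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @return Character vector of read sequences, names set to read ids.
#' @export
read_fastq_seqs <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L) {
    abort(paste0("Malformed FASTQ (", path, "): record count not multiple of 4."))
  }
  n <- length(lines) %/% 4L
  if (n == 0) return(character(0))
  idx <- seq_len(n)
  heads <- lines[4L * idx - 3L]
  if (any(substr(heads, 1L, 1L) != "@")) {
    abort(paste0("Malformed FASTQ (", path, "): header line without '@'."))
  }
  seqs <- toupper(lines[4L * idx - 2L])
  names(seqs) <- sub("^@", "", sub("\\s.*$", "", heads))
  seqs
}

#' Write sequences as FASTQ with constant quality
#'
#' @param seqs Character vector of sequences; names become read ids.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @param qual Single quality character recycled over all bases.
#' @return `path`, invisibly.
#' @export
write_fastq_seqs <- function(seqs, path, qual = "I") {
  ids <- names(seqs) %||% paste0("read", seq_along(seqs))
  recs <- as.vector(rbind(paste0("@", ids), unname(seqs), "+",
                          vapply(nchar(seqs),
                                 function(l) strrep(qual, l), character(1))))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(recs, con)
  invisible(path)
}
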