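# Cassette read processing: element extraction, tolerant matching against the
# library design, recombinant rejection, pegRNA counting and surrogate-target
# editing quantification.

#' Build the element layout of a pegRNA-ST cassette read pair
#'
#' Read 1 carries the pegRNA (spacer, scaffold, 3' extension); read 2 carries
#' the 55-nt surrogate target followed by the 16-nt pegRNA barcode and the
#' 10-nt library barcode, already oriented as stored in the library table.
#' Element boundaries are derived from the library design; extensions may vary
#' in length, so the extension slot spans the longest extension and matching
#' trims to each candidate's length.
#'
#' @param library A `pe_library`.
#' @param st_anchor_len Length of the invariant ST 3' end used for identity
#'   cross-checking (so edited STs still match their design).
#' @return A list of class `cassette_layout`.
#' @export
cassette_layout <- function(library, st_anchor_len = 15) {
  designs <- library$designs
  spacer_len <- unique(nchar(designs$spacer))
  if (length(spacer_len) != 1) {
    abort("All spacers must have equal length for fixed-offset extraction.")
  }
  scaffold_len <- unique(nchar(designs$scaffold))
  if (length(scaffold_len) != 1) {
    abort("All scaffolds must have equal length for fixed-offset extraction.")
  }
  ext_max <- max(nchar(designs$extension))
  st_len <- 55L
  bc_len <- 16L
  lbc_len <- 10L

  ids <- designs$pegrna_id
  st3p <- substr(designs$st_ref, st_len - st_anchor_len + 1L, st_len)
  candset <- function(seqs) {
    u <- unique(seqs)
    list(seqs = u, ids = split(ids, factor(seqs, levels = u)))
  }
  structure(list(
    spacer_len = spacer_len, scaffold_len = scaffold_len,
    ext_max = ext_max, st_len = st_len, bc_len = bc_len, lbc_len = lbc_len,
    st_anchor_len = as.integer(st_anchor_len),
    read1_min = spacer_len + scaffold_len + ext_max,
    read2_min = st_len + bc_len + lbc_len,
    anchor_seq = substr(designs$scaffold[1], 1L, 12L),
    anchor_pos = spacer_len + 1L,
    candidates = list(
      spacer = candset(designs$spacer),
      scaffold = candset(designs$scaffold),
      extension = candset(designs$extension),
      st3p = candset(st3p),
      pegrna_bc = candset(designs$pegrna_bc),
      library_bc = candset(designs$library_bc)
    )
  ), class = "cassette_layout")
}

#' Slice cassette elements out of read pairs
#'
#' Fixed-offset extraction with an optional anchor search: when
#' `anchor_slack > 0` the scaffold anchor is located within +/- `anchor_slack`
#' positions of its expected offset in read 1 (tolerating one substitution)
#' and all read-1 slices are shifted accordingly.
#'
#' @param reads1,reads2 Character vectors of read sequences (same length).
#' @param layout A [cassette_layout()].
#' @param anchor_slack Maximum shift searched for the read-1 anchor; 0
#'   disables the search.
#' @return A tibble with one row per pair: the six element slices and a
#'   `reject` column (`NA`, `"too_short"` or `"anchor_not_found"`).
#' @export
extract_elements <- function(reads1, reads2, layout, anchor_slack = 0) {
  stopifnot(length(reads1) == length(reads2))
  n <- length(reads1)
  reject <- rep(NA_character_, n)
  too_short <- nchar(reads1) < layout$read1_min |
    nchar(reads2) < layout$read2_min
  reject[too_short] <- "too_short"

  shift <- integer(n)
  if (anchor_slack > 0) {
    anchor <- layout$anchor_seq
    alen <- nchar(anchor)
    achars <- strsplit(anchor, "")[[1]]
    for (i in which(!too_short)) {
      best <- NA_integer_
      for (d in order(abs(seq(-anchor_slack, anchor_slack)))) {
        off <- seq(-anchor_slack, anchor_slack)[d]
        s <- substr(reads1[i], layout$anchor_pos + off,
                    layout$anchor_pos + off + alen - 1L)
        if (nchar(s) == alen &&
            sum(strsplit(s, "")[[1]] != achars) <= 1L) {
          best <- off
          break
        }
      }
      if (is.na(best)) reject[i] <- "anchor_not_found" else shift[i] <- best
    }
    # a shifted read needs the extra bases at its end
    still <- is.na(reject) &
      nchar(reads1) < layout$read1_min + pmax(shift, 0L)
    reject[still] <- "too_short"
  }

  sl <- layout$spacer_len
  scl <- layout$scaffold_len
  s1 <- 1L + shift
  tibble(
    spacer = substr(reads1, s1, s1 + sl - 1L),
    scaffold = substr(reads1, s1 + sl, s1 + sl + scl - 1L),
    extension = substr(reads1, s1 + sl + scl,
                       s1 + sl + scl + layout$ext_max - 1L),
    st = substr(reads2, 1L, layout$st_len),
    pegrna_bc = substr(reads2, layout$st_len + 1L,
                       layout$st_len + layout$bc_len),
    library_bc = substr(reads2, layout$st_len + layout$bc_len + 1L,
                        layout$read2_min),
    reject = reject
  )
}

hamming_dist <- function(a_chars, b_chars) sum(a_chars != b_chars)

#' Match an element sequence against its design candidates
#'
#' A candidate matches when its Hamming distance to the (trimmed) read slice
#' is at most `floor(mismatch_frac * candidate length)`; `N` bases count as
#' mismatches. Among matching candidates the one with minimal distance wins;
#' a tie at the minimal distance returns no match (identity is never
#' guessed).
#'
#' @param seqs Character vector of read slices.
#' @param candidates Character vector of candidate sequences (trimming is per
#'   candidate, so lengths may differ).
#' @param mismatch_frac Maximum substitution fraction per element.
#' @return Integer vector: index into `candidates`, or `NA` for no confident
#'   match.
#' @export
match_element <- function(seqs, candidates, mismatch_frac = 0.10) {
  if (length(candidates) == 0) abort("No candidates to match against.")
  n <- length(seqs)
  res <- rep(NA_integer_, n)
  lens <- nchar(candidates)
  # fast path: exact prefix match per candidate length; reads matching
  # exactly at more than one candidate length are re-examined by the full
  # distance scan so cross-length ties resolve to "no match"
  nhit <- integer(n)
  for (L in unique(lens)) {
    sub <- which(lens == L)
    hit <- match(substr(seqs, 1L, L), candidates[sub])
    found <- !is.na(hit)
    res[found & is.na(res)] <- sub[hit[found & is.na(res)]]
    nhit <- nhit + as.integer(found)
  }
  res[nhit > 1L] <- NA_integer_
  todo <- which(is.na(res) & !(nhit == 1L))
  if (length(todo) == 0) return(res)
  cand_chars <- strsplit(candidates, "")
  allowed <- floor(mismatch_frac * lens)
  seq_chars <- strsplit(seqs[todo], "")
  for (k in seq_along(todo)) {
    rc <- seq_chars[[k]]
    best_d <- Inf
    best_i <- NA_integer_
    tie <- FALSE
    for (j in seq_along(candidates)) {
      L <- lens[j]
      if (length(rc) < L) next
      d <- sum(rc[seq_len(L)] != cand_chars[[j]])
      if (d > allowed[j]) next
      if (d < best_d) {
        best_d <- d
        best_i <- j
        tie <- FALSE
      } else if (d == best_d) {
        tie <- TRUE
      }
    }
    if (!tie && !is.na(best_i)) res[todo[k]] <- best_i
  }
  res
}

# identity-bearing elements; scaffold and library barcode are shared across
# the library and carry no pegRNA identity
identity_elements <- function() c("spacer", "extension", "st3p", "pegrna_bc")

#' Classify extracted cassettes against the library
#'
#' Each identity-bearing element (spacer, 3' extension, the invariant ST 3'
#' end, pegRNA barcode) is matched with the configured mismatch tolerance and
#' contributes the set of pegRNAs consistent with it. A read is `assigned`
#' when the intersection of all confidently matched element sets is a single
#' pegRNA, `recombinant` when confidently matched elements are mutually
#' inconsistent (template-switched cassettes), and `unassigned` otherwise.
#' Only the ST 3' end is used for the surrogate target, so edited STs are not
#' discarded.
#'
#' @param elements Tibble from [extract_elements()].
#' @param layout A [cassette_layout()].
#' @param mismatch_frac Maximum substitution fraction per element.
#' @return A tibble with `status` (`assigned`/`recombinant`/`unassigned`/
#'   `rejected`) and `pegrna_id` (`NA` unless assigned), plus the `st` slice
#'   carried through for editing quantification.
#' @export
classify_cassette <- function(elements, layout, mismatch_frac = 0.10) {
  n <- nrow(elements)
  status <- rep("unassigned", n)
  pegrna_id <- rep(NA_character_, n)
  rejected <- !is.na(elements$reject)
  status[rejected] <- "rejected"

  ok <- which(!rejected)
  if (length(ok) > 0) {
    slices <- list(
      spacer = elements$spacer[ok],
      extension = elements$extension[ok],
      st3p = substr(elements$st[ok],
                    layout$st_len - layout$st_anchor_len + 1L, layout$st_len),
      pegrna_bc = elements$pegrna_bc[ok]
    )
    idsets <- lapply(identity_elements(), function(el) {
      cs <- layout$candidates[[el]]
      m <- match_element(slices[[el]], cs$seqs, mismatch_frac)
      lapply(seq_along(m), function(i) {
        if (is.na(m[i])) NULL else cs$ids[[m[i]]]
      })
    })
    for (k in seq_along(ok)) {
      sets <- lapply(idsets, function(x) x[[k]])
      sets <- sets[!vapply(sets, is.null, logical(1))]
      if (length(sets) == 0) next  # unassigned
      inter <- Reduce(intersect, sets)
      if (length(inter) == 1L) {
        status[ok[k]] <- "assigned"
        pegrna_id[ok[k]] <- inter
      } else if (length(inter) == 0L) {
        status[ok[k]] <- "recombinant"
      }  # >1: ambiguous, stays unassigned
    }
  }
  tibble(status = status, pegrna_id = pegrna_id, st = elements$st,
         reject = elements$reject)
}

#' Tally pegRNA counts and quantify surrogate-target editing
#'
#' Assigned reads are tallied per pegRNA. A surrogate target counts as
#' correctly edited when it contains the intended edit flanked by exactly
#' 5 nt on either side as an exact substring. Editing percentages are only
#' defined for pegRNAs with at least `min_st_reads` ST reads; every library
#' pegRNA is reported (zero counts included).
#'
#' @param classified Tibble from [classify_cassette()].
#' @param library A `pe_library`.
#' @param config A [screen_config()].
#' @param sample_id Sample identifier recorded in the output.
#' @return A tibble of per-pegRNA observations: `read_count`, `st_total`,
#'   `st_correct`, `st_editing_pct`.
#' @export
count_and_quantify <- function(classified, library, config,
                               sample_id = NA_character_) {
  designs <- library$designs
  asg <- classified[classified$status == "assigned", ]
  if (nrow(asg) > 0 && any(!asg$pegrna_id %in% designs$pegrna_id)) {
    abort("Assigned pegrna_id not present in the library.")
  }
  idx <- match(asg$pegrna_id, designs$pegrna_id)
  core <- designs$st_edit_core[idx]
  edited <- vapply(seq_len(nrow(asg)), function(i) {
    grepl(core[i], asg$st[i], fixed = TRUE)
  }, logical(1))
  counts <- tabulate(idx, nbins = nrow(designs))
  correct <- tabulate(idx[edited], nbins = nrow(designs))
  tibble(
    sample_id = sample_id,
    pegrna_id = designs$pegrna_id,
    read_count = counts,
    st_total = counts,
    st_correct = correct
  ) |>
    mutate(st_editing_pct = ifelse(.data$st_total >= config$min_st_reads,
                                   100 * .data$st_correct / .data$st_total,
                                   NA_real_))
}

#' Annotate observations with ST editing percentages
#'
#' Computes `st_editing_pct = 100 * st_correct / st_total`, defined only for
#' pegRNAs with at least `min_st_reads` ST reads. [count_and_quantify()]
#' does this for FASTQ-derived counts; this helper applies the same rule to
#' externally produced or simulated count tables.
#'
#' @param observations Tibble with `st_total` and `st_correct`.
#' @param config A [screen_config()].
#' @return The tibble with an `st_editing_pct` column.
#' @export
add_editing_pct <- function(observations, config) {
  mutate(observations,
         st_editing_pct = ifelse(.data$st_total >= config$min_st_reads,
                                 100 * .data$st_correct / .data$st_total,
                                 NA_real_))
}

#' Process one sample's cassette FASTQ pair end to end
#'
#' @param fastq1,fastq2 Paths to the paired FASTQ(.gz) files.
#' @param library A `pe_library`.
#' @param config A [screen_config()].
#' @param sample_id Sample identifier for the output table.
#' @param layout Optional pre-built [cassette_layout()].
#' @param anchor_slack Anchor search window for [extract_elements()].
#' @return List with `observations` (per-pegRNA tibble) and `read_stats`
#'   (tibble of read counts by classification status).
#' @export
process_cassette_fastq <- function(fastq1, fastq2, library, config,
                                   sample_id = NA_character_, layout = NULL,
                                   anchor_slack = 0) {
  layout <- layout %||% cassette_layout(library, config$st_anchor_len)
  r1 <- read_fastq_seqs(fastq1)
  r2 <- read_fastq_seqs(fastq2)
  if (length(r1) != length(r2)) {
    abort("Read 1 and read 2 FASTQ files differ in record count.")
  }
  elements <- extract_elements(r1, r2, layout, anchor_slack)
  classified <- classify_cassette(elements, layout,
                                  config$element_mismatch_frac)
  obs <- count_and_quantify(classified, library, config, sample_id)
  stats_tab <- classified |>
    count(.data$status, name = "reads") |>
    mutate(sample_id = sample_id, .before = 1)
  list(observations = obs, read_stats = stats_tab)
}

#' Exclude pegRNAs with background editing in the negative control
#'
#' pegRNAs whose ST editing in the editor-free negative-control sample
#' strictly exceeds the configured percentage are excluded from all
#' downstream analysis (their apparent editing reflects synthesis or
#' sequencing artefacts). Counts from replicate control samples are summed
#' before the percentage is computed. pegRNAs whose control editing is
#' undefined (fewer than `min_st_reads` control reads) are retained and
#' reported.
#'
#' @param observations Per-pegRNA observation tibble covering the control
#'   sample(s).
#' @param samples Validated sample tibble.
#' @param config A [screen_config()].
#' @return Character vector of excluded `pegrna_id`s, with attribute
#'   `undefined` listing pegRNAs whose control editing could not be assessed.
#' @export
negative_control_filter <- function(observations, samples, config) {
  ctrl_ids <- samples$sample_id[samples$role == "negative_control"]
  if (length(ctrl_ids) == 0) abort("No negative-control sample present.")
  ctrl <- observations |>
    filter(.data$sample_id %in% ctrl_ids) |>
    group_by(.data$pegrna_id) |>
    summarise(st_total = sum(.data$st_total),
              st_correct = sum(.data$st_correct), .groups = "drop") |>
    mutate(st_editing_pct = ifelse(.data$st_total >= config$min_st_reads,
                                   100 * .data$st_correct / .data$st_total,
                                   NA_real_))
  if (nrow(ctrl) == 0) abort("No negative-control observations found.")
  excluded <- ctrl$pegrna_id[!is.na(ctrl$st_editing_pct) &
                               ctrl$st_editing_pct >
                                 config$neg_ctrl_editing_max_pct]
  undefined <- ctrl$pegrna_id[is.na(ctrl$st_editing_pct)]
  inform(paste0("Negative-control filter: ", length(excluded),
                " pegRNA(s) excluded (> ", config$neg_ctrl_editing_max_pct,
                "% control editing); ", length(undefined),
                " with undefined control editing retained."))
  attr(excluded, "undefined") <- undefined
  excluded
}
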