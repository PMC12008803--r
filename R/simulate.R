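# Synthetic pooled PE screens with known ground truth.
#
# The generator reproduces the statistical structure the analysis assumes:
# a bimodal distribution of per-pegRNA editing rates, accumulation of editing
# over time in culture, selection acting multiplicatively on the edited
# subpopulation only, lentiviral cassette recombination, per-base sequencing
# error, and an editor-free negative control whose apparent editing is
# background only.

SP_SCAFFOLD <- paste0("GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACT",
                      "TGAAAAAGTGGCACCGAGTCGGTGC")
# constant downstream vector sequence used to pad reads to their fixed lengths
VECTOR_3P <- paste0("TGGAGGCTTGCTGAAGGCTGTATGCTGAATTCAAGCTTGGCGTAACTAGAT",
                    "CTTGAGACAAATGGCAGTATTCATCCACAATTTTAAAAGAAAAGGGGGGAT")

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
         character(1), USE.NAMES = FALSE)
}

#' Parameters of the synthetic screen generator
#'
#' Defaults describe the screen the rest of the package is benchmarked
#' against: 200 variants at 5 pegRNAs each (coverage capped at 9), per-pegRNA
#' editing rates drawn from a two-component Beta mixture whose modes mimic the
#' observed bimodality of sensor editing (an inactive mode near 0 and an
#' active mode near 1), editing accumulating by a factor `growth` per
#' timepoint unit, 15% of variants fully loss-of-function (effect `s_lof`
#' doublings per unit selection time), 30% hypomorphic with effects drawn
#' uniformly between 0.1 and 0.9 of `s_lof`, 2% cassette recombination, and a
#' 0.1% per-base substitution error.
#'
#' @param n_variants Number of variants in the library.
#' @param pegrnas_per_variant pegRNAs programming each variant; the library
#'   design caps coverage at `pegrna_cap`.
#' @param pegrna_cap Maximum pegRNA multiplicity per variant.
#' @param cap_action `"error"` rejects `pegrnas_per_variant > pegrna_cap`;
#'   `"clamp"` silently reduces to the cap.
#' @param editing_mixture List with `weights`, `shape1`, `shape2` of a
#'   two-component Beta mixture for baseline editing rates.
#' @param recombination_frac Fraction of emitted cassettes whose ST+barcode
#'   block is swapped with another random cassette (template switching).
#' @param seq_error_rate Per-base substitution error rate.
#' @param depth_per_sample Read pairs sequenced per sample.
#' @param growth Multiplicative accumulation of editing per timepoint unit:
#'   the editing probability at timepoint t is
#'   `min(1, e0 * growth^(t - t_pre))`.
#' @param selection_time Duration of selection in the units of the variant
#'   effect (doublings per unit time).
#' @param fraction_lof Fraction of variants with full loss-of-function effect.
#' @param fraction_intermediate Fraction of variants with intermediate
#'   (hypomorphic) effects.
#' @param s_lof Effect of a loss-of-function variant; negative for negative
#'   selection (depletion), positive for positive selection (enrichment).
#' @param background_edit_rate Apparent "editing" in the editor-free negative
#'   control (synthesis and sequencing artefacts).
#' @param abundance_sdlog Log-sd of the lognormal initial cassette abundance.
#' @param seed Integer seed; mandatory, all outputs are deterministic in it.
#'
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_variants = 200,
                       pegrnas_per_variant = 5,
                       pegrna_cap = 9,
                       cap_action = c("error", "clamp"),
                       editing_mixture = list(weights = c(0.45, 0.55),
                                              shape1 = c(0.3, 5),
                                              shape2 = c(3, 1.5)),
                       recombination_frac = 0.02,
                       seq_error_rate = 0.001,
                       depth_per_sample = 5e5,
                       growth = 1.4,
                       selection_time = 3,
                       fraction_lof = 0.15,
                       fraction_intermediate = 0.30,
                       s_lof = -2,
                       background_edit_rate = 0.001,
                       abundance_sdlog = 0.5,
                       seed) {
  cap_action <- match.arg(cap_action)
  if (missing(seed) || is.null(seed)) {
    abort("sim_params() requires an explicit integer seed.")
  }
  stopifnot(
    n_variants >= 2, pegrnas_per_variant >= 1, pegrna_cap >= 1,
    recombination_frac >= 0, recombination_frac <= 1,
    seq_error_rate >= 0, seq_error_rate < 1,
    depth_per_sample >= 1, growth > 0, selection_time > 0,
    fraction_lof >= 0, fraction_lof <= 1,
    fraction_intermediate >= 0, fraction_lof + fraction_intermediate <= 1,
    background_edit_rate >= 0, background_edit_rate < 1,
    length(editing_mixture$weights) == 2,
    abs(sum(editing_mixture$weights) - 1) < 1e-8
  )
  if (pegrnas_per_variant > pegrna_cap) {
    if (cap_action == "error") {
      abort(paste0("pegrnas_per_variant exceeds the coverage cap (",
                   pegrna_cap, "); use cap_action = 'clamp' to reduce."))
    }
    pegrnas_per_variant <- pegrna_cap
  }
  structure(
    list(n_variants = as.integer(n_variants),
         pegrnas_per_variant = as.integer(pegrnas_per_variant),
         pegrna_cap = as.integer(pegrna_cap),
         editing_mixture = editing_mixture,
         recombination_frac = recombination_frac,
         seq_error_rate = seq_error_rate,
         depth_per_sample = as.integer(depth_per_sample),
         growth = growth,
         selection_time = selection_time,
         fraction_lof = fraction_lof,
         fraction_intermediate = fraction_intermediate,
         s_lof = s_lof,
         background_edit_rate = background_edit_rate,
         abundance_sdlog = abundance_sdlog,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

rbeta_mixture <- function(n, mix) {
  comp <- sample(seq_along(mix$weights), n, replace = TRUE,
                 prob = mix$weights)
  stats::rbeta(n, mix$shape1[comp], mix$shape2[comp])
}

#' Simulate a pegRNA-ST library with known truth
#'
#' Generates a full library design (random spacers, the canonical SpCas9
#' scaffold, variable-length 3' extensions, per-variant 55-nt surrogate
#' targets with a single-nucleotide intended edit placed away from the
#' invariant 3' end, unique 16-nt pegRNA barcodes and a shared 10-nt library
#' barcode) together with the latent truth behind it: each pegRNA's baseline
#' editing rate drawn from the bimodal mixture, and each variant's selection
#' effect and class.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `pe_sim` with elements `library` (a `pe_library`),
#'   `truth` (tibbles `pegrna` and `variant`), and `params`.
#' @export
simulate_library <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  nv <- params$n_variants
  k <- params$pegrnas_per_variant
  n <- nv * k
  if (n > 4^10) abort("Barcode space exhausted for this library size.")

  n_lof <- round(params$fraction_lof * nv)
  n_int <- round(params$fraction_intermediate * nv)
  cls <- sample(c(rep("lof", n_lof), rep("intermediate", n_int),
                  rep("neutral", nv - n_lof - n_int)))
  effect <- numeric(nv)
  effect[cls == "lof"] <- params$s_lof
  effect[cls == "intermediate"] <-
    params$s_lof * stats::runif(sum(cls == "intermediate"), 0.1, 0.9)
  consequence <- character(nv)
  consequence[cls == "lof"] <-
    sample(c("nonsense", "canonical_splice"), n_lof, replace = TRUE)
  consequence[cls == "intermediate"] <- "missense"
  consequence[cls == "neutral"] <- "synonymous"

  variant_id <- sprintf("VAR_%04d", seq_len(nv))
  st_ref <- random_dna(nv, 55)
  edit_pos <- sample(15:30, nv, replace = TRUE)
  ref_base <- substr(st_ref, edit_pos, edit_pos)
  alt_base <- other_base(ref_base)
  st_edit_core <- paste0(substr(st_ref, edit_pos - 5, edit_pos - 1), alt_base,
                         substr(st_ref, edit_pos + 1, edit_pos + 5))

  variants <- tibble(
    variant_id = variant_id,
    gene = "SIMGENE",
    genomic_pos = 1000L + seq_len(nv),
    consequence = consequence,
    clinvar = "none",
    neutral_set = consequence == "synonymous",
    plof_set = consequence %in% c("nonsense", "canonical_splice")
  )

  pegrna_bc <- unique(random_dna(n * 2, 16))[seq_len(n)]
  if (length(pegrna_bc) < n || anyDuplicated(pegrna_bc) > 0) {
    abort("Failed to draw unique pegRNA barcodes.")
  }
  library_bc <- random_dna(1, 10)
  pbs_len <- sample(8:15, n, replace = TRUE)
  rtt_len <- sample(10:30, n, replace = TRUE)
  extension <- vapply(pbs_len + rtt_len, function(l) random_dna(1, l),
                      character(1))
  vidx <- rep(seq_len(nv), each = k)
  designs <- tibble(
    pegrna_id = sprintf("PEG_%05d", seq_len(n)),
    variant_id = variant_id[vidx],
    spacer = random_dna(n, 20),
    scaffold = SP_SCAFFOLD,
    extension = extension,
    st_ref = st_ref[vidx],
    st_edit_core = st_edit_core[vidx],
    pegrna_bc = pegrna_bc,
    library_bc = library_bc,
    pbs_length = pbs_len,
    rtt_length = rtt_len,
    rtt_homology_length = pmax(rtt_len - sample(1:5, n, replace = TRUE), 1),
    nick_to_edit_distance = sample(0:20, n, replace = TRUE),
    pbs_gc_fraction = vapply(seq_len(n), function(i) {
      p <- substr(extension[i], 1, pbs_len[i])
      mean(strsplit(p, "")[[1]] %in% c("G", "C"))
    }, numeric(1)),
    spacer_ontarget_score = stats::runif(n)
  )

  truth_pegrna <- tibble(
    pegrna_id = designs$pegrna_id,
    variant_id = designs$variant_id,
    true_editing_rate = rbeta_mixture(n, params$editing_mixture),
    edit_start = (edit_pos - 5L)[vidx],
    abundance = stats::rlnorm(n, 0, params$abundance_sdlog)
  )
  truth_variant <- tibble(variant_id = variant_id, effect = effect,
                          true_class = cls)

  structure(list(library = new_pe_library(designs, variants),
                 truth = list(pegrna = truth_pegrna, variant = truth_variant),
                 params = params),
            class = "pe_sim")
}

#' Default sample sheet for a simulated screen
#'
#' Single mode: one condition with a negative control and a pre sample at the
#' first timepoint and a post sample after selection. Multi mode: two cell
#' lines crossed with co-selection (four conditions), sharing one negative
#' control, mirroring a four-pool positive-selection design.
#'
#' @param mode `"single"` or `"multi"`.
#' @param t_pre,t_post Timepoints (in editing-accumulation units) of the pre-
#'   and post-selection harvests.
#' @param screen_id Screen identifier.
#' @return A validated sample tibble.
#' @export
sim_sample_sheet <- function(mode = c("single", "multi"),
                             t_pre = 1, t_post = 4, screen_id = "SIM") {
  mode <- match.arg(mode)
  conds <- if (mode == "single") {
    tibble(cell_line = "HAP1", coselection = FALSE)
  } else {
    tidyr::expand_grid(cell_line = c("HAP1_PEmax", "HAP1_PEmaxdn"),
                       coselection = c(FALSE, TRUE))
  }
  per_cond <- purrr::pmap_dfr(conds, function(cell_line, coselection) {
    tibble(cell_line = cell_line, coselection = coselection,
           timepoint = c(t_pre, t_post), role = c("pre", "post"))
  })
  nc <- tibble(cell_line = conds$cell_line[1], coselection = FALSE,
               timepoint = t_pre, role = "negative_control")
  tab <- bind_rows(per_cond, nc) |>
    mutate(replicate = 1L, screen_id = screen_id,
           sample_id = paste0(screen_id, "_",
                              sample_condition(.data$cell_line,
                                               .data$coselection),
                              "_t", .data$timepoint, "_", .data$role,
                              "_r", .data$replicate))
  validate_samples(tab)
}

# latent editing probability of each pegRNA at timepoint t (relative to the
# pre timepoint, where the mixture draw applies directly)
editing_at <- function(e0, t, t_ref, growth) {
  pmin(1, e0 * growth^(t - t_ref))
}

# relative fitness of a cassette population: selection acts only on the
# edited subpopulation, multiplying it by 2^(s * selection_time)
selection_weight <- function(e, s, selection_time) {
  (1 - e) + e * 2^(s * selection_time)
}

#' Simulate sequencing of a pooled PE screen
#'
#' For every sample, pegRNA read counts are drawn multinomially from latent
#' cassette abundances (lognormal library representation, reweighted in
#' post-selection samples by the fitness of each pegRNA's edited
#' subpopulation) and the number of correctly edited surrogate targets is
#' binomial in the sample-specific editing probability. Negative-control
#' samples see background "editing" only. When `outdir` is given the drawn
#' counts are additionally realised as paired FASTQ reads (read 1: spacer,
#' scaffold, 3' extension; read 2: ST, pegRNA barcode, library barcode; both
#' padded with constant vector sequence), with cassette recombination and
#' per-base substitution errors applied on top.
#'
#' @param sim A `pe_sim` object from [simulate_library()].
#' @param samples A validated sample tibble, e.g. [sim_sample_sheet()].
#' @param outdir Directory for FASTQ output, or `NULL` for counts only.
#' @param gzip Compress FASTQ output.
#' @return A list with `observations` (the emitted truth: per sample and
#'   pegRNA, `read_count`, `st_total`, `st_correct`), `sample_truth`
#'   (per-sample latent editing probabilities), and `fastq` (tibble of file
#'   paths, or `NULL`).
#' @export
simulate_screen <- function(sim, samples, outdir = NULL, gzip = TRUE) {
  stopifnot(inherits(sim, "pe_sim"))
  params <- sim$params
  if (params$depth_per_sample < 1) abort("Sequencing depth must be positive.")
  set.seed(params$seed + 1L)
  designs <- sim$library$designs
  tp <- sim$truth$pegrna
  eff <- sim$truth$variant$effect[match(tp$variant_id,
                                        sim$truth$variant$variant_id)]
  t_ref <- min(samples$timepoint[samples$role == "pre"])

  per_sample <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    smp <- samples[i, ]
    if (smp$role == "negative_control") {
      p_edit <- rep(params$background_edit_rate, nrow(tp))
      ab <- tp$abundance
    } else {
      e_t <- editing_at(tp$true_editing_rate, smp$timepoint, t_ref,
                        params$growth)
      if (smp$role == "post") {
        w <- selection_weight(e_t, eff, params$selection_time)
        ab <- tp$abundance * w
        # among surviving cells of this pegRNA, the edited fraction shifts
        # with the same selection factor
        p_edit <- e_t * 2^(eff * params$selection_time) / w
      } else {
        ab <- tp$abundance
        p_edit <- e_t
      }
    }
    counts <- as.integer(stats::rmultinom(1, params$depth_per_sample,
                                          ab / sum(ab)))
    st_correct <- stats::rbinom(length(counts), counts, p_edit)
    per_sample[[i]] <- tibble(
      sample_id = smp$sample_id,
      pegrna_id = tp$pegrna_id,
      read_count = counts,
      st_total = counts,
      st_correct = st_correct,
      p_edit = p_edit
    )
  }
  obs <- bind_rows(per_sample)
  sample_truth <- obs |> select("sample_id", "pegrna_id", "p_edit")
  obs$p_edit <- NULL

  fq <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fq <- emit_fastq(obs, sim, samples, outdir, gzip)
  }
  list(observations = obs, sample_truth = sample_truth, fastq = fq)
}

st_edited_seq <- function(st_ref, st_edit_core, edit_start) {
  paste0(substr(st_ref, 1, edit_start - 1), st_edit_core,
         substr(st_ref, edit_start + nchar(st_edit_core), nchar(st_ref)))
}

apply_seq_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    chars <- strsplit(seqs[i], "")[[1]]
    chars[pos] <- other_base(chars[pos])
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

emit_fastq <- function(obs, sim, samples, outdir, gzip) {
  designs <- sim$library$designs
  tp <- sim$truth$pegrna
  params <- sim$params
  read1_len <- 182L
  read2_len <- 118L
  r1_design <- vapply(seq_len(nrow(designs)), function(i) {
    s <- paste0(designs$spacer[i], designs$scaffold[i], designs$extension[i])
    paste0(s, substr(VECTOR_3P, 1, read1_len - nchar(s)))
  }, character(1))
  st_unedited <- designs$st_ref
  st_edited <- st_edited_seq(designs$st_ref, designs$st_edit_core,
                             tp$edit_start[match(designs$pegrna_id,
                                                 tp$pegrna_id)])
  r2_block <- function(st) {
    s <- paste0(st, designs$pegrna_bc, designs$library_bc)
    paste0(s, substr(rep(VECTOR_3P, length(s)), 1, read2_len - nchar(s)))
  }
  r2_unedited <- r2_block(st_unedited)
  r2_edited <- r2_block(st_edited)

  ext <- if (gzip) ".fastq.gz" else ".fastq"
  out <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    smp <- samples[i, ]
    o <- obs[obs$sample_id == smp$sample_id, ]
    idx <- match(o$pegrna_id, designs$pegrna_id)
    reads_idx <- rep(idx, o$read_count)
    edited <- unlist(lapply(seq_len(nrow(o)), function(j) {
      c(rep(TRUE, o$st_correct[j]), rep(FALSE, o$read_count[j] - o$st_correct[j]))
    }))
    ord <- sample.int(length(reads_idx))
    reads_idx <- reads_idx[ord]
    edited <- edited[ord]
    r1 <- r1_design[reads_idx]
    r2 <- ifelse(edited, r2_edited[reads_idx], r2_unedited[reads_idx])
    if (params$recombination_frac > 0) {
      rec <- stats::runif(length(r2)) < params$recombination_frac
      if (any(rec)) {
        partner <- vapply(reads_idx[rec], function(k) {
          sample(setdiff(seq_len(nrow(designs)), k), 1)
        }, integer(1))
        r2[rec] <- r2_unedited[partner]
      }
    }
    r1 <- apply_seq_errors(r1, params$seq_error_rate)
    r2 <- apply_seq_errors(r2, params$seq_error_rate)
    ids <- sprintf("%s_%07d", smp$sample_id, seq_along(r1))
    names(r1) <- ids
    names(r2) <- ids
    f1 <- file.path(outdir, paste0(smp$sample_id, "_R1", ext))
    f2 <- file.path(outdir, paste0(smp$sample_id, "_R2", ext))
    write_fastq_seqs(r1, f1)
    write_fastq_seqs(r2, f2)
    out[[i]] <- tibble(sample_id = smp$sample_id, fastq1 = f1, fastq2 = f2)
  }
  bind_rows(out)
}

#' Simulate endogenous-target (ET) variant count tables
#'
#' Variant-level genomic frequencies are the pegRNA abundance model aggregated
#' over each variant's pegRNAs: the frequency of a variant in the amplicon
#' pool is the edited-cell mass of its pegRNAs over total cell mass, with
#' selection reweighting edited cells in post-selection samples. Every sample
#' additionally sees a per-variant background frequency (site-specific
#' sequencing error, lognormal across variants); the negative control sample
#' contains background only.
#'
#' @param sim A `pe_sim` object.
#' @param samples A validated sample tibble.
#' @param depth Total ET reads per sample (defaults to the cassette depth).
#' @param background_meanlog,background_sdlog Lognormal parameters of the
#'   per-variant background frequency.
#' @return A tibble with one row per (variant, sample): `count`, `depth`,
#'   `freq`.
#' @export
simulate_et_counts <- function(sim, samples, depth = NULL,
                               background_meanlog = log(4e-5),
                               background_sdlog = 1) {
  stopifnot(inherits(sim, "pe_sim"))
  params <- sim$params
  depth <- depth %||% params$depth_per_sample
  set.seed(params$seed + 2L)
  tp <- sim$truth$pegrna
  tv <- sim$truth$variant
  eff <- tv$effect[match(tp$variant_id, tv$variant_id)]
  t_ref <- min(samples$timepoint[samples$role == "pre"])
  bg <- stats::rlnorm(nrow(tv), background_meanlog, background_sdlog)
  names(bg) <- tv$variant_id

  rows <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    smp <- samples[i, ]
    if (smp$role == "negative_control") {
      fv <- stats::setNames(rep(0, nrow(tv)), tv$variant_id)
    } else {
      e_t <- editing_at(tp$true_editing_rate, smp$timepoint, t_ref,
                        params$growth)
      if (smp$role == "post") {
        sel <- 2^(eff * params$selection_time)
        edited_mass <- tp$abundance * e_t * sel
        total_mass <- sum(tp$abundance * selection_weight(e_t, eff,
                                                          params$selection_time))
      } else {
        edited_mass <- tp$abundance * e_t
        total_mass <- sum(tp$abundance)
      }
      fv <- tapply(edited_mass, tp$variant_id, sum) / total_mass
      fv <- fv[tv$variant_id]
    }
    p <- fv + bg
    p_wt <- max(0, 1 - sum(p))
    counts <- as.integer(stats::rmultinom(1, depth, c(p, p_wt)))
    rows[[i]] <- tibble(variant_id = tv$variant_id,
                        sample_id = smp$sample_id,
                        count = counts[seq_len(nrow(tv))],
                        depth = depth)
  }
  bind_rows(rows) |> mutate(freq = .data$count / .data$depth)
}
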