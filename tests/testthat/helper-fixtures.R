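# Fixtures and independent oracles shared across the suite. Oracles are
# deliberately naive re-implementations (brute force / literal formulas),
# kept free of any package internals they are used to check.

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_base <- function(seq, pos, to = NULL) {
  chars <- strsplit(seq, "")[[1]]
  for (i in seq_along(pos)) {
    old <- chars[pos[i]]
    chars[pos[i]] <- if (is.null(to)) setdiff(c("A", "C", "G", "T"), old)[1]
    else to[i]
  }
  paste(chars, collapse = "")
}

# a hand-sized library: 3 variants (synonymous / nonsense / missense),
# one pegRNA each, written as a TSV and read back through the validator
tiny_library_table <- function(seed = 42) {
  set.seed(seed)
  st_ref <- rand_dna(3, 55)
  edit_pos <- c(20, 22, 25)
  alt <- vapply(seq_len(3), function(i) {
    setdiff(c("A", "C", "G", "T"),
            substr(st_ref[i], edit_pos[i], edit_pos[i]))[1]
  }, character(1))
  core <- vapply(seq_len(3), function(i) {
    paste0(substr(st_ref[i], edit_pos[i] - 5, edit_pos[i] - 1), alt[i],
           substr(st_ref[i], edit_pos[i] + 1, edit_pos[i] + 5))
  }, character(1))
  data.frame(
    pegrna_id = paste0("peg", 1:3),
    variant_id = paste0("var", 1:3),
    spacer = rand_dna(3, 20),
    scaffold = rep(rand_dna(1, 30), 3),
    extension = rand_dna(3, 20),
    st_ref = st_ref,
    st_edit_core = core,
    pegrna_bc = rand_dna(3, 16),
    library_bc = rep(rand_dna(1, 10), 3),
    gene = "G1",
    genomic_pos = 101:103,
    consequence = c("synonymous", "nonsense", "missense"),
    stringsAsFactors = FALSE
  )
}

write_library_tsv <- function(tab, path = tempfile(fileext = ".tsv")) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

tiny_library <- function(seed = 42) {
  read_library(write_library_tsv(tiny_library_table(seed)))
}

# build a full-length read pair straight from a design row
design_read_pair <- function(design, layout, edited = FALSE,
                             edit_start = NULL) {
  filler <- strrep("T", 300)
  st <- design$st_ref
  if (edited) {
    stopifnot(!is.null(edit_start))
    st <- paste0(substr(st, 1, edit_start - 1), design$st_edit_core,
                 substr(st, edit_start + nchar(design$st_edit_core),
                        nchar(st)))
  }
  r1 <- paste0(design$spacer, design$scaffold, design$extension, filler)
  r2 <- paste0(st, design$pegrna_bc, design$library_bc, filler)
  list(r1 = substr(r1, 1, layout$read1_min + 5),
       r2 = substr(r2, 1, layout$read2_min + 5))
}

# ---- independent oracles ----------------------------------------------

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# literal minimum-distance matcher: candidate qualifies at distance
# <= floor(frac * its length) on the slice trimmed to its length; ties at
# the minimal distance (including exact ties across lengths) give no match
oracle_match <- function(seq, candidates, frac = 0.10) {
  d <- vapply(candidates, function(cand) {
    L <- nchar(cand)
    if (nchar(seq) < L) return(Inf)
    dist <- oracle_hamming(substr(seq, 1, L), cand)
    if (dist > floor(frac * L)) Inf else dist
  }, numeric(1))
  if (all(is.infinite(d))) return(NA_integer_)
  best <- unname(which(d == min(d)))
  if (length(best) > 1) NA_integer_ else as.integer(best)
}

# brute-force cassette classifier over every element and every design
oracle_classify <- function(reads1, reads2, library, config,
                            st_anchor_len = 15) {
  designs <- library$designs
  sl <- nchar(designs$spacer[1])
  scl <- nchar(designs$scaffold[1])
  ext_max <- max(nchar(designs$extension))
  frac <- config$element_mismatch_frac
  st3p_all <- substr(designs$st_ref, 55 - st_anchor_len + 1, 55)
  out_status <- character(length(reads1))
  out_id <- rep(NA_character_, length(reads1))
  for (i in seq_along(reads1)) {
    if (nchar(reads1[i]) < sl + scl + ext_max ||
        nchar(reads2[i]) < 81) {
      out_status[i] <- "rejected"
      next
    }
    slices <- list(
      spacer = substr(reads1[i], 1, sl),
      extension = substr(reads1[i], sl + scl + 1, sl + scl + ext_max),
      st3p = substr(reads2[i], 55 - st_anchor_len + 1, 55),
      pegrna_bc = substr(reads2[i], 56, 71)
    )
    cand <- list(spacer = designs$spacer, extension = designs$extension,
                 st3p = st3p_all, pegrna_bc = designs$pegrna_bc)
    sets <- list()
    for (el in names(slices)) {
      u <- unique(cand[[el]])
      m <- oracle_match(slices[[el]], u, frac)
      if (!is.na(m)) {
        sets[[el]] <- designs$pegrna_id[cand[[el]] == u[m]]
      }
    }
    if (length(sets) == 0) {
      out_status[i] <- "unassigned"
    } else {
      inter <- Reduce(intersect, sets)
      if (length(inter) == 1) {
        out_status[i] <- "assigned"
        out_id[i] <- inter
      } else if (length(inter) == 0) {
        out_status[i] <- "recombinant"
      } else {
        out_status[i] <- "unassigned"
      }
    }
  }
  data.frame(status = out_status, pegrna_id = out_id,
             stringsAsFactors = FALSE)
}

# literal BH step-up: q_(i) = min_{j >= i} p_(j) * n / j, capped at 1
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

# exhaustive pairwise AUC, ties count one half
oracle_auc <- function(is_pos, scores) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Spearman via explicit mid-ranks
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# default single-condition simulated screen, counts annotated with editing
sim_screen_fixture <- function(seed, params = NULL, mode = "single",
                               config = screen_config(scoring_mode = "single")) {
  p <- params %||% sim_params(seed = seed)
  sim <- simulate_library(p)
  smp <- sim_sample_sheet(mode)
  scr <- simulate_screen(sim, smp)
  obs <- add_editing_pct(scr$observations, config)
  list(sim = sim, samples = smp, screen = scr, obs = obs, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built two-condition screen: 6 variants x 3 pegRNAs, 5 neutral
# variants with 1 pegRNA each for the normalisation baseline
toy_multi_screen <- function() {
  lib_tab <- tiny_library_table(seed = 99)
  # extend to 11 variants: v1 (target, missense), v2-v6 neutral, v7 pLoF,
  # plus v8-v11 extra targets; each variant 1-3 pegRNAs
  set.seed(99)
  n_per <- c(3, 1, 1, 1, 1, 1, 3, 2, 2, 2, 2)
  cons <- c("missense", rep("synonymous", 5), "nonsense",
            rep("missense", 4))
  rows <- do.call(rbind, lapply(seq_along(n_per), function(v) {
    k <- n_per[v]
    st <- rand_dna(1, 55)
    core <- paste0(substr(st, 15, 19), "A", substr(st, 21, 25))
    if (core == substr(st, 15, 25)) {
      core <- paste0(substr(st, 15, 19), "C", substr(st, 21, 25))
    }
    data.frame(
      pegrna_id = sprintf("pg%02d_%d", v, seq_len(k)),
      variant_id = sprintf("v%02d", v),
      spacer = rand_dna(k, 20), scaffold = rep(rand_dna(1, 30), k),
      extension = rand_dna(k, 20), st_ref = st, st_edit_core = core,
      pegrna_bc = rand_dna(k, 16), library_bc = "ACGTACGTAC",
      gene = "G", genomic_pos = 100 + v, consequence = cons[v]
    )
  }))
  read_library(write_library_tsv(rows))
}

toy_score_table <- function(lib, scores_c1, scores_c2) {
  ids <- lib$designs$pegrna_id
  build <- function(cond, sc) {
    keep <- !is.na(sc)
    tibble::tibble(
      condition = cond, pegrna_id = ids[keep],
      freq_pre = 1e-3, freq_post = 1e-3,
      pegrna_score = sc[keep], st_editing_pre_pct = 90,
      passed_freq_filter = TRUE, passed_activity_filter = TRUE,
      retained = TRUE
    )
  }
  dplyr::bind_rows(build("c1", scores_c1), build("c2", scores_c2))
}

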