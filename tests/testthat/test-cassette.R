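test_that("element extraction recovers the design and rejects short reads", {
  lib <- tiny_library()
  layout <- cassette_layout(lib)
  d <- lib$designs[1, ]
  rp <- design_read_pair(d, layout)
  el <- extract_elements(rp$r1, rp$r2, layout)
  expect_true(is.na(el$reject))
  expect_equal(el$spacer, d$spacer)
  expect_equal(el$scaffold, d$scaffold)
  expect_equal(substr(el$extension, 1, nchar(d$extension)), d$extension)
  expect_equal(el$st, d$st_ref)
  expect_equal(el$pegrna_bc, d$pegrna_bc)
  expect_equal(el$library_bc, d$library_bc)

  short <- extract_elements(rp$r1, substr(rp$r2, 1, 60), layout)
  expect_equal(short$reject, "too_short")
})

test_that("anchor search recovers elements from shifted reads", {
  lib <- tiny_library()
  layout <- cassette_layout(lib)
  d <- lib$designs[2, ]
  rp <- design_read_pair(d, layout)
  shifted <- paste0("G", rp$r1)  # 1-nt insertion upstream of the cassette
  miss <- extract_elements(shifted, rp$r2, layout, anchor_slack = 0)
  expect_false(identical(miss$spacer, d$spacer))
  hit <- extract_elements(shifted, rp$r2, layout, anchor_slack = 2)
  expect_true(is.na(hit$reject))
  expect_equal(hit$spacer, d$spacer)
  expect_equal(substr(hit$extension, 1, nchar(d$extension)), d$extension)
})

test_that("element matching follows the floor(10%) Hamming rule", {
  set.seed(7)
  bcs <- rand_dna(20, 16)
  expect_equal(match_element(bcs[3], bcs), 3L)
  one_sub <- mutate_base(bcs[3], 5)
  expect_equal(match_element(one_sub, bcs), 3L)          # floor(1.6) = 1
  two_sub <- mutate_base(bcs[3], c(5, 9))
  expect_true(is.na(match_element(two_sub, bcs)))
  with_n <- mutate_base(bcs[3], c(2, 11), to = c("N", "N"))
  expect_true(is.na(match_element(with_n, bcs)))         # N is a mismatch

  # tie at equal minimal distance gives no match
  a <- "ACGTACGTACGTACGTACGT"
  b <- mutate_base(a, 1)
  probe <- mutate_base(a, 3)  # distance 1 to a, could also be 2 to b
  expect_equal(match_element(probe, c(a, b)), 1L)
  mid <- mutate_base(a, 1, to = "N")  # N: distance 1 to both
  expect_true(is.na(match_element(mid, c(a, b))))
})

test_that("matching agrees with the brute-force oracle on random probes", {
  set.seed(11)
  cands <- rand_dna(15, 16)
  for (i in 1:200) {
    base <- sample(cands, 1)
    nmut <- sample(0:3, 1)
    probe <- if (nmut > 0) mutate_base(base, sample(16, nmut)) else base
    got <- match_element(probe, cands)
    want <- oracle_match(probe, cands)
    expect_identical(is.na(got), is.na(want))
    if (!is.na(got)) expect_equal(got, want)
  }
})

test_that("cassette classification assigns, flags recombinants, or abstains", {
  lib <- tiny_library()
  layout <- cassette_layout(lib)
  cfg <- screen_config()
  dA <- lib$designs[1, ]
  dB <- lib$designs[2, ]
  rpA <- design_read_pair(dA, layout)
  rpB <- design_read_pair(dB, layout)

  clean <- classify_cassette(extract_elements(rpA$r1, rpA$r2, layout),
                             layout, cfg$element_mismatch_frac)
  expect_equal(clean$status, "assigned")
  expect_equal(clean$pegrna_id, dA$pegrna_id)

  # pegRNA half from A, ST + barcode block from B: template switching
  rec <- classify_cassette(extract_elements(rpA$r1, rpB$r2, layout),
                           layout, cfg$element_mismatch_frac)
  expect_equal(rec$status, "recombinant")

  # an edited ST still matches its design through the invariant 3' end
  ed <- design_read_pair(dA, layout, edited = TRUE, edit_start = 15)
  edited <- classify_cassette(extract_elements(ed$r1, ed$r2, layout),
                              layout, cfg$element_mismatch_frac)
  expect_equal(edited$status, "assigned")

  # spacer intact, every other identity element degraded beyond tolerance
  mangle <- function(s, k) mutate_base(s, seq_len(k))
  r1 <- paste0(dA$spacer, dA$scaffold, mangle(dA$extension, 5),
               strrep("T", 100))
  r2 <- paste0(mangle(dA$st_ref, 55), mangle(dA$pegrna_bc, 4),
               dA$library_bc, strrep("T", 50))
  un <- classify_cassette(extract_elements(r1, r2, layout), layout,
                          cfg$element_mismatch_frac)
  expect_equal(un$status, "assigned")  # spacer alone pins the identity
  expect_equal(un$pegrna_id, dA$pegrna_id)

  # mangle the spacer too: nothing matches confidently
  r1b <- paste0(mangle(dA$spacer, 5), dA$scaffold, mangle(dA$extension, 5),
                strrep("T", 100))
  un2 <- classify_cassette(extract_elements(r1b, r2, layout), layout,
                           cfg$element_mismatch_frac)
  expect_equal(un2$status, "unassigned")
})

test_that("editing is quantified by exact edit-core containment", {
  lib <- tiny_library()
  layout <- cassette_layout(lib)
  cfg <- screen_config()
  d <- lib$designs[1, ]
  core_start <- 15L

  mk <- function(n_edit, n_unedited, tweak_flank = FALSE) {
    reads <- c(replicate(n_edit, {
      rp <- design_read_pair(d, layout, edited = TRUE,
                             edit_start = core_start)
      rp$r2
    }), replicate(n_unedited, design_read_pair(d, layout)$r2))
    if (tweak_flank && n_edit > 0) {
      reads[1] <- mutate_base(reads[1], core_start)  # first flank base
    }
    r1 <- replicate(n_edit + n_unedited, design_read_pair(d, layout)$r1)
    cls <- classify_cassette(extract_elements(r1, reads, layout), layout,
                             cfg$element_mismatch_frac)
    count_and_quantify(cls, lib, cfg, sample_id = "s")
  }

  obs <- mk(5, 5)
  row <- obs[obs$pegrna_id == d$pegrna_id, ]
  expect_equal(row$st_total, 10)
  expect_equal(row$st_correct, 5)
  expect_equal(row$st_editing_pct, 50)

  undef <- mk(4, 5)  # 9 reads: below the 10-read floor
  expect_true(is.na(undef$st_editing_pct[undef$pegrna_id == d$pegrna_id]))

  flank <- mk(5, 5, tweak_flank = TRUE)
  expect_equal(flank$st_correct[flank$pegrna_id == d$pegrna_id], 4)
})

test_that("negative-control filter uses the strict 5% rule", {
  lib <- tiny_library()
  cfg <- screen_config()
  smp <- data.frame(sample_id = "nc", cell_line = "HAP1",
                    coselection = FALSE, timepoint = 1, replicate = 1L,
                    role = "negative_control", screen_id = "S1")
  smp <- validate_samples(rbind(
    smp,
    data.frame(sample_id = c("pre", "post"), cell_line = "HAP1",
               coselection = FALSE, timepoint = c(1, 4), replicate = 1L,
               role = c("pre", "post"), screen_id = "S1")))
  obs <- tibble::tibble(
    sample_id = "nc",
    pegrna_id = c("peg1", "peg2", "peg3"),
    read_count = c(100L, 100L, 5L),
    st_total = c(100L, 100L, 5L),
    st_correct = c(5L, 7L, 3L)
  )
  obs <- add_editing_pct(obs, cfg)
  expect_message(excl <- negative_control_filter(obs, smp, cfg),
                 "1 pegRNA")
  expect_equal(as.character(excl), "peg2")      # 7% > 5%
  expect_false("peg1" %in% excl)                # exactly 5%: retained
  expect_equal(attr(excl, "undefined"), "peg3") # < 10 reads: logged
})

test_that("classification conserves reads and ignores read order", {
  p <- sim_params(n_variants = 10, pegrnas_per_variant = 2,
                  depth_per_sample = 3000, recombination_frac = 0.1,
                  seq_error_rate = 0.01, seed = 3)
  sim <- simulate_library(p)
  smp <- sim_sample_sheet("single")
  scr <- simulate_screen(sim, smp, outdir = tempfile("fqo"), gzip = FALSE)
  cfg <- screen_config()
  layout <- cassette_layout(sim$library)
  r1 <- read_fastq_seqs(scr$fastq$fastq1[1])
  r2 <- read_fastq_seqs(scr$fastq$fastq2[1])
  cls <- classify_cassette(extract_elements(r1, r2, layout), layout,
                           cfg$element_mismatch_frac)
  expect_equal(nrow(cls), length(r1))
  expect_setequal(unique(cls$status),
                  intersect(c("assigned", "recombinant", "unassigned",
                              "rejected"), unique(cls$status)))
  obs <- count_and_quantify(cls, sim$library, cfg, "s")

  set.seed(1)
  perm <- sample(length(r1))
  cls2 <- classify_cassette(extract_elements(r1[perm], r2[perm], layout),
                            layout, cfg$element_mismatch_frac)
  obs2 <- count_and_quantify(cls2, sim$library, cfg, "s")
  expect_equal(obs, obs2)
})
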