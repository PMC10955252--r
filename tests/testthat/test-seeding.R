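# SMEM collection: SuperMEM1, whole-read sweep, re-seeding, seed
# materialisation. Oracle = exhaustive maximal-substring enumeration with
# naive occurrence counts.

test_that("a unique read gives one whole-read SMEM and one valid seed", {
  set.seed(31)
  g <- random_genome(2000)
  idx <- fmd_index(c(chr = g))
  read <- substring(g, 501, 550)  # 50-mer, 0-based position 500
  og <- oracle_genome(g)
  skip_if(oracle_count(og, read) != 1)  # seed choice guarantees uniqueness
  sd <- smem_seeder(idx)
  sm <- super_mem1(sd, read, 0, 1)
  expect_equal(nrow(sm), 1)
  expect_equal(c(sm$qbeg, sm$qend, sm$s), c(0, 50, 1))
  seeds <- seed_reads(smem_seeder(idx), read)
  expect_equal(nrow(seeds), 1)
  expect_equal(seeds$rbeg, 500)
  expect_equal(seeds$strand, "+")
  expect_true(all(check_seeds(idx, seeds, read)))
})

test_that("a dead pivot base yields no SMEMs", {
  idx <- fmd_index(c(chr = strrep("A", 100)))
  sd <- smem_seeder(idx)
  read <- paste0(strrep("A", 10), "C", strrep("A", 10))
  expect_equal(nrow(super_mem1(sd, read, 10, 1)), 0)
  # but an A pivot in the same read still finds matches
  expect_gt(nrow(super_mem1(sd, read, 2, 1)), 0)
})

test_that("super_mem1 equals the exhaustive pivot-covering oracle", {
  set.seed(41)
  for (inst in 1:4) {
    g <- random_genome(sample(800:2000, 1))
    og <- oracle_genome(g)
    idx <- fmd_index(c(chr = g))
    sd <- smem_seeder(idx, cache = inst %% 2 == 0)
    reads <- draw_reads(g, 5, 100, error_rate = 0.01, rc_frac = 0.3)
    for (read in reads) {
      for (pivot in seq(0, 99, by = 13)) {
        for (mi in c(1, 2)) {
          got <- super_mem1(sd, read, pivot, mi)
          want <- oracle_maximal_matches(og, read, t = mi, pivot = pivot)
          expect_equal(smem_key(got), smem_key(want),
                       info = sprintf("inst %d pivot %d min_intv %d",
                                      inst, pivot, mi))
        }
      }
    }
  }
})

test_that("a mid-read substitution splits the read into flanking SMEMs", {
  set.seed(43)
  g <- random_genome(2000)
  og <- oracle_genome(g)
  idx <- fmd_index(c(chr = g))
  read <- substring(g, 701, 800)
  old <- substring(read, 50, 50)
  substring(read, 50, 50) <- setdiff(c("A", "C", "G", "T"), old)[1]
  sd <- smem_seeder(idx)
  sm <- collect_smems(sd, read)
  want <- oracle_collect(og, read)
  expect_equal(smem_key(sm), smem_key(want))
  # the two flanks: one SMEM starting at 0 ending near the error, one
  # ending at 100 starting near the error
  expect_true(any(sm$qbeg == 0 & sm$qend < 100))
  expect_true(any(sm$qend == 100 & sm$qbeg > 0))
})

test_that("re-seeding recovers repeat copies hidden inside long SMEMs", {
  set.seed(47)
  g <- random_genome(3000)
  unit <- substring(g, 1001, 1060)
  substring(g, 2001, 2060) <- unit
  substring(g, 2501, 2560) <- unit
  # distinct flanking bases so no copy extends the repeat match
  substring(g, 1000, 1000) <- "A"; substring(g, 1061, 1061) <- "A"
  substring(g, 2000, 2000) <- "C"; substring(g, 2061, 2061) <- "C"
  substring(g, 2500, 2500) <- "G"; substring(g, 2561, 2561) <- "G"
  og <- oracle_genome(g)
  idx <- fmd_index(c(chr = g))
  read <- substring(g, 981, 1080)  # repeat occupies read offsets [20, 80)
  sd <- smem_seeder(idx)
  sm <- collect_smems(sd, read)
  expect_equal(smem_key(sm), smem_key(oracle_collect(og, read)))
  rs <- sm[sm$origin == "reseed", , drop = FALSE]
  expect_gt(nrow(rs), 0)
  expect_true(any(rs$s >= 3))
  # the multi-copy match materialises one seed per occurrence
  seeds <- seed_reads(smem_seeder(idx), read)
  expect_true(all(check_seeds(idx, seeds, read)))
  expect_true(any(seeds$origin == "reseed"))
  multi <- seeds[seeds$intv_size >= 3, , drop = FALSE]
  expect_true(all(c(1000, 2000, 2500) %in% multi$rbeg))
})

test_that("re-seeding is not triggered below the length threshold", {
  set.seed(53)
  g <- random_genome(2000)
  idx <- fmd_index(c(chr = g))
  read <- substring(g, 301, 325)  # 25 < 19 * 1.5
  sd <- smem_seeder(idx)
  sm <- collect_smems(sd, read)
  expect_true(all(sm$origin == "smem"))
})

test_that("matches over max_occ are skipped entirely", {
  set.seed(59)
  core <- random_genome(25)
  g <- paste0(random_genome(300), strrep(core, 8), random_genome(300))
  idx <- fmd_index(c(chr = g))
  read <- core
  capped <- seeding_params(min_seed_len = 10, max_occ = 5)
  seeds_capped <- seed_reads(smem_seeder(idx, capped), read)
  open <- seeding_params(min_seed_len = 10, max_occ = 500)
  seeds_open <- seed_reads(smem_seeder(idx, open), read)
  # every match kept under the cap must also exist uncapped, and the
  # high-occurrence matches present uncapped are absent when capped
  expect_true(all(seeds_capped$intv_size <= 5))
  expect_gt(max(seeds_open$intv_size), 5)
  expect_true(all(check_seeds(idx, seeds_open, read)))
})

test_that("seeding is deterministic and seeds stay valid on N-split reads", {
  set.seed(61)
  g <- random_genome(5000)
  idx <- fmd_index(c(chr = g))
  reads <- draw_reads(g, 40, 100, error_rate = 0.01, rc_frac = 0.5)
  # inject an N run into a few reads; segments are seeded independently
  substring(reads[3], 40, 42) <- "NNN"
  substring(reads[7], 1, 1) <- "N"
  a <- seed_reads(smem_seeder(idx), reads)
  b <- seed_reads(smem_seeder(idx), reads)
  expect_identical(a, b)
  expect_true(all(check_seeds(idx, a, reads)))
  expect_true(all(a$qend - a$qbeg >= 19))
  # no seed spans the injected N run of read 3
  r3 <- a[a$read_id == "read3", , drop = FALSE]
  expect_true(all(r3$qend <= 39 | r3$qbeg >= 42))
})

test_that("a more permissive reseed factor never removes seeds", {
  set.seed(67)
  g <- random_genome(4000)
  unit <- substring(g, 501, 540)
  substring(g, 3001, 3040) <- unit  # some duplicated sequence
  idx <- fmd_index(c(chr = g))
  reads <- draw_reads(g, 50, 100, error_rate = 0.005, rc_frac = 0.5)
  key <- function(df) paste(df$read_id, df$qbeg, df$qend, df$strand, df$rbeg)
  tight <- seed_reads(smem_seeder(idx, seeding_params(reseed_r = 1.5)), reads)
  loose <- seed_reads(smem_seeder(idx, seeding_params(reseed_r = 1.2)), reads)
  expect_true(all(key(tight) %in% key(loose)))
})
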