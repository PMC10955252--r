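# SMEM search tries and SAL merging: cache hits, lazy fills, batch
# resets, transparency, savings bounds.

counters <- function(sd) unlist(seeder_counters(sd))

test_that("repeated queries are cache hits; dead ends are cached too", {
  g <- random_genome(500, seed = 71)
  idx <- fmd_index(c(chr = g))
  sd <- smem_seeder(idx, cache = TRUE)
  c0 <- counters(sd)
  q1 <- sst_forward_query(sd, 1, "C")  # extend "A" to "AC"
  c1 <- counters(sd)
  expect_equal(c1["bwt_queries"] - c0["bwt_queries"], c(bwt_queries = 1))
  expect_equal(c1["bwt_real"] - c0["bwt_real"], c(bwt_real = 1))
  q2 <- sst_forward_query(sd, 1, "C")
  c2 <- counters(sd)
  expect_identical(q2, q1)
  expect_equal(c2["bwt_real"], c1["bwt_real"])  # hit: no real access
  expect_equal(c2["bwt_queries"] - c1["bwt_queries"], c(bwt_queries = 1))
  # cached interval equals the uncached extension
  direct <- bwt_extend(idx, base_interval(idx, "A"), "C", "forward")
  expect_equal(q1$interval, as.numeric(direct), ignore_attr = TRUE)

  # drive a pattern to extinction; the dead end costs once, repeats free
  node <- 1
  iv <- base_interval(idx, "A")
  depth <- 1
  while (iv[["s"]] > 0 && depth < 20) {
    r <- sst_forward_query(sd, node, "A")
    node <- r$node
    iv <- r$interval
    depth <- depth + 1
  }
  expect_equal(unname(iv[["s"]]), 0)
  cb <- counters(sd)
  parent <- sst_nodes(sd)$parent[node + 1]
  rep1 <- sst_forward_query(sd, parent, "A")
  ca <- counters(sd)
  expect_equal(ca["bwt_real"], cb["bwt_real"])
  expect_equal(rep1$interval[["s"]], 0)
})

test_that("a duplicated read is answered without real forward accesses", {
  g <- random_genome(2000, seed = 73)
  idx <- fmd_index(c(chr = g))
  sd <- smem_seeder(idx, cache = TRUE)
  read <- substring(g, 301, 400)
  invisible(collect_smems(sd, read))
  c1 <- counters(sd)
  invisible(collect_smems(sd, read))
  c2 <- counters(sd)
  expect_equal(c2["bwt_real"], c1["bwt_real"])  # zero real accesses
  expect_equal(c2["bwt_queries"] - c1["bwt_queries"], c1["bwt_queries"],
               ignore_attr = TRUE)  # same query stream as the first pass
})

test_that("reverse-order insertion creates unknown interim nodes", {
  g <- random_genome(400, seed = 79)
  idx <- fmd_index(c(chr = g))
  sd <- smem_seeder(idx, cache = TRUE)
  iv <- pattern_interval(idx, "ACAA")
  term <- sst_backward_insert(sd, "ACAA", iv)
  nd <- sst_nodes(sd, backward = TRUE)
  # path root -> A -> A -> C -> A spells (reversed) "ACAA"; the nodes for
  # "AA" and "CAA" are created with unknown interval (size -1)
  expect_equal(nrow(nd), 5 + 3)  # root + 4 precomputed + 3 new
  expect_equal(sum(nd$s == -1), 2)
  expect_equal(nd$s[term + 1], unname(iv[["s"]]))
  # no FM access during insertion
  expect_equal(counters(sd)[["bwt_real"]], 0)

  # single-base match: terminal is a precomputed root child, nothing new
  t2 <- sst_backward_insert(sd, "G", base_interval(idx, "G"))
  expect_lte(t2, 4)
  expect_equal(nrow(sst_nodes(sd, backward = TRUE)), nrow(nd))
  # idempotent re-insertion
  t3 <- sst_backward_insert(sd, "ACAA", iv)
  expect_equal(t3, term)
  expect_equal(nrow(sst_nodes(sd, backward = TRUE)), nrow(nd))
})

test_that("unknown nodes are filled top-down with counted accesses", {
  g <- random_genome(400, seed = 83)
  idx <- fmd_index(c(chr = g))
  sd <- smem_seeder(idx, cache = TRUE)
  iv <- pattern_interval(idx, "ACAA")
  invisible(sst_backward_insert(sd, "ACAA", iv))
  nd <- sst_nodes(sd, backward = TRUE)
  # locate the unknown depth-3 node spelling "CAA" (path A -> A -> C)
  n_a <- nd$child_A[1]
  n_aa <- nd$child_A[n_a + 1]
  n_caa <- nd$child_C[n_aa + 1]
  expect_equal(nd$s[n_aa + 1], -1)
  expect_equal(nd$s[n_caa + 1], -1)
  c0 <- counters(sd)
  r <- sst_backward_query(sd, n_caa, "T")
  c1 <- counters(sd)
  # 2 lazy fills ("AA", then "CAA") + 1 extension to "TCAA"
  expect_equal(unname(c1["bwt_real"] - c0["bwt_real"]), 3)
  expect_equal(unname(c1["bwt_queries"] - c0["bwt_queries"]), 1)
  expect_equal(as.numeric(r$interval),
               as.numeric(pattern_interval(idx, "TCAA")),
               ignore_attr = TRUE)
  # repeat costs nothing real
  r2 <- sst_backward_query(sd, n_caa, "T")
  c2 <- counters(sd)
  expect_equal(c2["bwt_real"], c1["bwt_real"])
  expect_identical(r2, r)
  # the fills cached the true intervals of the interim nodes
  nd2 <- sst_nodes(sd, backward = TRUE)
  expect_equal(nd2$s[n_aa + 1], unname(pattern_interval(idx, "AA")[["s"]]))
  expect_equal(nd2$s[n_caa + 1], unname(pattern_interval(idx, "CAA")[["s"]]))
})

test_that("SAL merging performs one real lookup per distinct rank", {
  g <- random_genome(1000, seed = 89)
  idx <- fmd_index(c(chr = g))
  sd <- smem_seeder(idx, cache = TRUE, sal_merge = TRUE)
  # identical intervals: s real lookups total, not 2s
  for (r in 10:19) sal_resolve(sd, r)
  c1 <- counters(sd)
  for (r in 10:19) sal_resolve(sd, r)
  c2 <- counters(sd)
  expect_equal(unname(c1[c("sal_queries", "sal_real")]), c(10, 10))
  expect_equal(unname(c2[c("sal_queries", "sal_real")]), c(20, 10))
  # overlapping intervals [10,20) and [15,25): union has 15 ranks
  for (r in 15:24) sal_resolve(sd, r)
  c3 <- counters(sd)
  expect_equal(unname(c3["sal_real"]), 15)
  # random batch: real lookups equal the union of requested rank ranges
  set.seed(90)
  ranges <- replicate(30, {
    a <- sample.int(500, 1); c(a, a + sample.int(20, 1))
  })
  for (j in seq_len(ncol(ranges))) {
    for (r in ranges[1, j]:(ranges[2, j] - 1)) sal_resolve(sd, r)
  }
  c4 <- counters(sd)
  union_size <- length(unique(unlist(
    apply(ranges, 2, function(x) x[1]:(x[2] - 1), simplify = FALSE))))
  expect_equal(unname(c4["sal_real"] - c3["sal_real"]),
               length(setdiff(unique(unlist(
                 apply(ranges, 2, function(x) x[1]:(x[2] - 1),
                       simplify = FALSE))), c(10:24))))
  # resolved positions agree with the plain index lookup
  expect_equal(sal_resolve(sd, 42), sal(idx, 42))
})

test_that("batch reset clears the caches but preserves counters", {
  g <- random_genome(1000, seed = 97)
  idx <- fmd_index(c(chr = g))
  sd <- smem_seeder(idx, cache = TRUE)
  invisible(sst_forward_query(sd, 1, "C"))
  invisible(sal_resolve(sd, 5))
  c1 <- counters(sd)
  batch_reset(sd)
  expect_equal(nrow(sst_nodes(sd)), 5)            # root + 4 children
  expect_equal(nrow(sst_nodes(sd, backward = TRUE)), 5)
  expect_equal(counters(sd), c1)                  # cumulative counters kept
  invisible(sst_forward_query(sd, 1, "C"))        # real again after reset
  invisible(sal_resolve(sd, 5))
  c2 <- counters(sd)
  expect_equal(unname(c2["bwt_real"] - c1["bwt_real"]), 1)
  expect_equal(unname(c2["sal_real"] - c1["sal_real"]), 1)
})

test_that("caching is transparent and never increases real accesses", {
  cfg <- sim_config(genome_length = 20000, coverage = 5, error_rate = 0.005,
                    seed = 101)
  genome <- simulate_genome(cfg)
  reads <- reorder_reads(simulate_reads(genome, cfg), "oracle")  # 1000 reads
  idx <- fmd_index(c(sim = genome))
  on <- run_seeding(idx, reads, cache = TRUE, sal_merge = TRUE)
  off <- run_seeding(idx, reads, cache = FALSE, sal_merge = FALSE)
  expect_identical(on$seeds, off$seeds)
  expect_identical(on$stats$totals$bwt_queries, off$stats$totals$bwt_queries)
  expect_lte(on$stats$totals$bwt_real, off$stats$totals$bwt_real)
  expect_lte(on$stats$totals$sal_real, off$stats$totals$sal_real)
  expect_true(all(check_seeds(idx, on$seeds, setNames(reads$read, reads$id))))

  # batch size changes counters but never the seeds
  p2 <- seeding_params(batch_size = 1024L)
  on2 <- run_seeding(idx, reads, p2, cache = TRUE, sal_merge = TRUE)
  expect_identical(on2$seeds, on$seeds)
  expect_lte(on2$stats$totals$bwt_real, on$stats$totals$bwt_real)
  expect_false(identical(on2$stats$totals, on$stats$totals))
})
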