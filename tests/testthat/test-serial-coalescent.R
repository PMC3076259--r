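# Simulator checks against coalescent theory: tip/time structure, pairwise
# TMRCA, Tavaré's ancestral lineage counts, deme isolation, determinism.

test_that("simulated genealogies have the declared tip and time structure", {
  cfg <- validate_config(admixture_model(2000, c = 0.1), sampling_scheme(),
                         time_scale(2))
  tr <- simulate_genealogy(cfg, seed = 5)
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 312)
  expect_equal(tr$Nnode, 311)
  expect_equal(sum(tr$tip.epoch == "ancient"), 13)
  # epoch ultrametricity: modern tips at 0, ancient tips at the converted age
  expect_true(all(tr$node.time[which(tr$tip.epoch == "modern")] == 0))
  expect_true(all(tr$node.time[which(tr$tip.epoch == "ancient")] == 500))
  # parents strictly older than children, edge lengths consistent
  expect_true(all(tr$node.time[tr$edge[, 1]] > tr$node.time[tr$edge[, 2]]))
  expect_equal(tr$edge.length,
               tr$node.time[tr$edge[, 1]] - tr$node.time[tr$edge[, 2]])
  expect_true(ape::is.binary(tr))
})

test_that("a single sampled lineage yields a degenerate genealogy", {
  cfg <- validate_config(constant_model(100), sampling_scheme(1, 0, 0))
  tr <- simulate_genealogy(cfg, seed = 1)
  expect_equal(length(tr$tip.label), 1)
  expect_equal(tr$Nnode, 0)
  expect_equal(nrow(tr$edge), 0)
})

test_that("identical seeds reproduce genealogies and statistics bit-exactly", {
  cfg <- validate_config(admixture_model(1000, c = 0.2), sampling_scheme(30, 5, 1000))
  a <- simulate_genealogy(cfg, seed = 9, replicate = 3)
  b <- simulate_genealogy(cfg, seed = 9, replicate = 3)
  expect_identical(a$edge, b$edge)
  expect_identical(a$node.time, b$node.time)
  d <- simulate_genealogy(cfg, seed = 9, replicate = 4)
  expect_false(identical(a$node.time, d$node.time))
  p1 <- estimate_probability(cfg, k = 3, reps = 500, seed = 7)
  p2 <- estimate_probability(cfg, k = 3, reps = 500, seed = 7)
  expect_identical(p1$p_hat, p2$p_hat)
})

test_that("pairwise TMRCA matches the constant-size expectation E[T2] = Ne", {
  ne <- 1000
  reps <- 5000
  cfg <- validate_config(constant_model(ne), sampling_scheme(2, 0, 0))
  tm <- unlist(simulate_batch(cfg, reps, seed = 21, FUN = tmrca))
  se <- stats::sd(tm) / sqrt(reps)
  expect_lt(abs(mean(tm) - ne), 3 * se)
})

test_that("ancestral lineage counts match Tavaré's series", {
  # exact series against an independent matrix-exponential of the death chain
  n <- 20
  rates <- choose(n:2, 2)
  Q <- matrix(0, n, n) # states n..1
  for (i in seq_len(n - 1)) {
    Q[i, i] <- -rates[i]
    Q[i, i + 1] <- rates[i]
  }
  for (tau in c(0.05, 0.2, 1)) {
    P <- Matrix::expm(Q * tau)
    expected <- sum(as.numeric(P[1, ]) * (n:1))
    expect_equal(expected_ancestor_count(n, 1, tau), expected,
                 tolerance = 1e-8)
  }
  # headline configuration: 299 lineages, Ne = 3000, 500 generations
  expect_gt(expected_ancestor_count(299, 3000, 500), 10)
  expect_lt(expected_ancestor_count(299, 3000, 500), 14)
  expect_equal(expected_ancestor_count(5, 1234, 0), 5)
  expect_equal(expected_ancestor_count(2, 1000, 1e9), 1, tolerance = 1e-6)

  # simulator agreement at several time points
  ne <- 3000
  reps <- 1200
  cfg <- validate_config(constant_model(ne), sampling_scheme(299, 0, 0))
  for (t in c(200, 500, 1500)) {
    lc <- unlist(simulate_batch(cfg, reps, seed = 31 + t,
                                FUN = function(tr) lineages_at(tr, t)))
    se <- stats::sd(lc) / sqrt(reps)
    expect_lt(abs(mean(lc) - expected_ancestor_count(299, ne, t)), 3 * se)
  }
})

test_that("demes stay isolated between the split and the join", {
  # with c = 0 no modern lineage enters the New World deme, so no node may
  # mix ancient and modern ancestry before the join
  cfg <- validate_config(admixture_model(2000, c = 0), sampling_scheme(50, 13, 1000),
                         time_scale(2))
  t_join <- cfg$cpp$t_join
  t_split <- cfg$cpp$t_split
  for (r in 1:25) {
    tr <- simulate_genealogy(cfg, seed = 77, replicate = r)
    n <- length(tr$tip.label)
    anc <- c(as.integer(tr$tip.epoch == "ancient"), integer(tr$Nnode))
    mod <- c(as.integer(tr$tip.epoch == "modern"), integer(tr$Nnode))
    edge <- ape::reorder.phylo(tr, "postorder")$edge
    for (e in seq_len(nrow(edge))) {
      p <- edge[e, 1]; ch <- edge[e, 2]
      anc[p] <- anc[p] + anc[ch]
      mod[p] <- mod[p] + mod[ch]
    }
    internal <- (n + 1):(n + tr$Nnode)
    mixed <- internal[anc[internal] > 0 & mod[internal] > 0]
    expect_true(all(tr$node.time[mixed] >= t_join))
    # New World coalescences happen only while the deme exists
    nw <- internal[tr$node.deme == 1]
    expect_true(all(tr$node.time[nw] >= t_split & tr$node.time[nw] <= t_join))
  }
})

test_that("full admixture (c = 1) collapses to the constant model", {
  ne <- 3000
  reps <- 8000
  samp <- sampling_scheme()
  ts <- time_scale(2)
  pc <- estimate_probability(validate_config(constant_model(ne), samp, ts),
                             reps = reps, seed = 5)
  pa <- estimate_probability(
    validate_config(admixture_model(ne, c = 1), samp, ts),
    reps = reps, seed = 6)
  se <- sqrt(pc$standard_error^2 + pa$standard_error^2)
  expect_lt(abs(pc$p_hat - pa$p_hat), 4 * se)
})

test_that("batch indicators agree with statistics computed on full trees", {
  cfg <- validate_config(constant_model(800), sampling_scheme(60, 13, 1000),
                         time_scale(2))
  for (st in c("single", "pooled")) {
    ind <- sim_stat_batch_cpp(cfg$cpp, 40L, 19, 0, 6L,
                              match(st, c("single", "pooled")) - 1L)
    tree_ind <- vapply(0:39, function(r) {
      tr <- simulate_genealogy(cfg, seed = 19, replicate = r)
      evaluate_statistic(tr, k = 6, statistic = st)$indicator
    }, logical(1))
    expect_identical(as.logical(ind), tree_ind)
  }
})

test_that("genealogies round-trip through Newick", {
  cfg <- validate_config(constant_model(500), sampling_scheme(10, 4, 1000))
  trees <- simulate_batch(cfg, 3, seed = 8)
  file <- withr::local_tempfile(fileext = ".nwk")
  write_genealogies(trees, file)
  back <- read_genealogies(file)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(sort(back[[i]]$tip.label), sort(trees[[i]]$tip.label))
    expect_identical(back[[i]]$tip.epoch[order(back[[i]]$tip.label)],
                     trees[[i]]$tip.epoch[order(trees[[i]]$tip.label)])
    expect_equal(tmrca(back[[i]]), tmrca(trees[[i]]), tolerance = 1e-6)
    expect_equal(max_exclusive_ancient_clade(back[[i]]),
                 max_exclusive_ancient_clade(trees[[i]]))
  }
})
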