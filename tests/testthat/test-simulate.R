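test_that("gBGC tilt rescales WS and SW fluxes exactly", {
  code <- genetic_code()
  m <- yn98_model(2, 0.3, matrix(0.25, 3, 4))
  expect_equal(gbgc_tilt(m$Q, 1), m$Q, tolerance = 1e-15,
               ignore_attr = TRUE)
  Qt <- gbgc_tilt(m$Q, 2)
  ws <- !is.na(code$gc_class) & code$gc_class == 1L
  sw <- !is.na(code$gc_class) & code$gc_class == 2L
  cons <- !is.na(code$gc_class) & code$gc_class >= 3L
  expect_equal(Qt[ws], 2 * m$Q[ws], tolerance = 1e-14)
  expect_equal(Qt[sw], m$Q[sw] / 2, tolerance = 1e-14)
  expect_equal(Qt[cons], m$Q[cons], tolerance = 1e-15)
  expect_lt(max(abs(rowSums(Qt))), 1e-12)
  # stationary GC of the tilted chain increases with gamma
  statgc <- vapply(c(1, 2, 4), function(g) {
    Qg <- gbgc_tilt(m$Q, g)
    v <- Re(eigen(t(Qg))$vectors[, 61])
    v <- v / sum(v)
    ngc <- vapply(strsplit(code$codons, ""),
                  function(x) sum(x %in% c("G", "C")), 0L)
    sum(v * ngc) / 3
  }, numeric(1L))
  expect_true(all(diff(statgc) > 0))
  expect_equal(b_to_gamma(0), 1)
  expect_equal(b_to_gamma(2), exp(1))
})

test_that("fixation-form branch generator reduces to YN98 at B = 0", {
  pi <- f3x4_frequencies(matrix(0.25, 3, 4))
  Q0 <- condnds:::.gbgc_branch_generator(2, 0.2, pi, 0)
  expect_equal(Q0, build_yn98_matrix(2, 0.2, pi), tolerance = 1e-14)
  # at B > 0, WS boost is proportionally larger for non-synonymous
  code <- genetic_code()
  QB <- condnds:::.gbgc_branch_generator(2, 0.2, pi, 2)
  ws_s <- !is.na(code$gc_class) & code$gc_class == 1L & !code$nonsyn &
    code$single
  ws_n <- !is.na(code$gc_class) & code$gc_class == 1L & code$nonsyn
  boost_s <- QB[ws_s] / build_yn98_matrix(2, 0.2, pi)[ws_s]
  boost_n <- QB[ws_n] / build_yn98_matrix(2, 0.2, pi)[ws_n]
  expect_gt(min(boost_n), max(boost_s) + 0.1)
  # conservative rates untouched
  cons <- !is.na(code$gc_class) & code$gc_class >= 3L
  expect_equal(QB[cons], build_yn98_matrix(2, 0.2, pi)[cons],
               tolerance = 1e-14)
})

test_that("zero-length trees return the root sequence everywhere", {
  tr <- balanced8(0)
  tr$edge.length[] <- 0
  cfg <- sim_config(tr, n_codons = 50L, seed = 2L)
  sim <- simulate_alignment(cfg)
  for (i in seq_len(nrow(sim$alignment$states)))
    expect_equal(unname(sim$alignment$states[i, ]),
                 sim$truth$root_seq)
  expect_equal(sum(sim$truth$counts), 0)
})

test_that("realized substitution counts follow the Poisson expectation", {
  # one long branch at omega = 1, gamma = 1: total events ~ Poisson(L t)
  tr <- ape::read.tree(text = "(A:0.3,B:0.0);")
  tr$edge.length[tr$edge.length == 0] <- 1e-9
  cfg <- sim_config(tr, kappa = 2, omega = 1, n_codons = 5000L,
                    seed = 14L)
  sim <- simulate_alignment(cfg)
  n_ev <- sum(sim$truth$counts)
  lambda <- 5000 * 0.3  # generator normalized to rate 1 at equilibrium
  expect_lt(abs(n_ev - lambda), 3 * sqrt(lambda))
})

test_that("simulation is deterministic and replayable", {
  tr <- balanced8()
  cfg <- sim_config(tr, n_codons = 120L, seed = 9L)
  s1 <- simulate_alignment(cfg)
  s2 <- simulate_alignment(cfg)
  expect_identical(s1$alignment$states, s2$alignment$states)
  expect_identical(s1$truth$counts, s2$truth$counts)
  # replaying the event log reproduces the tips exactly
  rp <- replay_events(s1$truth)
  expect_identical(rp[rownames(s1$alignment$states), ],
                   s1$alignment$states)
  # event categories agree with classify_substitution
  ev <- s1$truth$events
  code <- genetic_code()
  idx <- sample(nrow(ev), min(50L, nrow(ev)))
  for (k in idx) {
    cl <- classify_substitution(code$codons[ev$from[k]],
                                code$codons[ev$to[k]])
    expect_equal(ev$category[k],
                 paste(if (cl$coding_class == "synonymous") "syn"
                       else "nonsyn", cl$gc_class, sep = "_"))
  }
})

test_that("tip GC at 4-fold sites approaches the process equilibrium on
           long branches", {
  # gamma = 2 (B = 2 log 2): WS/SW flux ratio e^B = 4 at neutral sites,
  # so equilibrium GC at 4-fold sites ~ 0.8; gamma = 1 stays at 0.5
  tr <- ape::read.tree(text = "(A:5,B:5);")
  for (g in c(1, 2)) {
    cfg <- sim_config(tr, kappa = 2, omega = 0.3, gamma = g,
                      n_codons = 1500L, seed = 33L)
    sim <- simulate_alignment(cfg)
    st <- sim$alignment$states["A", ]
    gc4 <- gc_at_degenerate_sites(st, "4fold")
    if (g == 1) expect_lt(abs(gc4 - 0.5), 0.06)
    else expect_gt(gc4, 0.7)
  }
})

test_that("generated traits track omega and are reproducible", {
  tr <- balanced8()
  om <- stats::setNames(seq(0.1, 0.45, length.out = 8L),
                        tr$tip.label)
  t1 <- generate_traits(tr, om, slope = 1, noise_sd = 0, seed = 4L)
  expect_equal(order(t1$body_mass_g),
               order(om[t1$species]))
  t2 <- generate_traits(tr, om, slope = 1, noise_sd = 0, seed = 4L)
  expect_identical(t1, t2)
  # slope 0: traits unlinked to omega
  t3 <- generate_traits(tr, om, slope = 0, noise_sd = 0.3, seed = 4L)
  expect_lt(abs(cor(log10(t3$body_mass_g), log(om[t3$species]))), 0.9)
  expect_true(all(t1$body_mass_g > 0))
})

test_that("gene sets exercise every binning scheme", {
  tr <- balanced8()
  gs <- make_gene_set(tr, n_genes = 12L, codons_per_gene = 60L,
                      seed = 6L)
  expect_length(gs$alignments, 12L)
  expect_equal(nrow(gs$genes), 12L)
  # GC regimes separate: rank split recovers regime membership
  spec <- gc_rank_split(gs$genes, 2L)
  regime <- gs$genes$gc_regime[match(spec$gene_id, gs$genes$gene_id)]
  expect_equal(mean((spec$gc_group == "high") == (regime == "rich")), 1)
  # chromosome split discards intermediates only
  cs <- chromosome_split(gs$genes)
  inter <- gs$genes$gene_id[gs$genes$chromosome_mb >= 16 &
                              gs$genes$chromosome_mb <= 100]
  expect_true(!any(inter %in% cs$gene_id))
  # per-gene mean GC reflects the configured regimes
  rich_gc <- gs$genes$mean_gc[gs$genes$gc_regime == "rich"]
  poor_gc <- gs$genes$mean_gc[gs$genes$gc_regime == "poor"]
  expect_gt(mean(rich_gc), 0.55)
  expect_lt(mean(poor_gc), 0.45)
})
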