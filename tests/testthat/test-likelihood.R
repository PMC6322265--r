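test_that("pruning equals brute-force enumeration on small trees", {
  th <- matrix(0.25, 3, 4)
  rho <- matrix(c(0.4, 0.2, 0.2, 0.2,
                  0.25, 0.25, 0.25, 0.25,
                  0.2, 0.2, 0.3, 0.3), 3, 4, byrow = TRUE)
  model <- yn98_model(2, 0.4, th, rho = rho)
  cases <- list(
    list(tree = "((A:0.2,B:0.3):0.15,C:0.4);",
         seqs = c(A = "AAATTTGGA", B = "AAGTTAGGA", C = "CAATTGGGC")),
    list(tree = "(A:0.1,B:0.5);",
         seqs = c(A = "ATGCCC", B = "ATACCA")),
    list(tree = "((A:0.05,B:0.1):0.2,C:0.02);",
         seqs = c(A = "TTT---CCC", B = "TTAGGGCCC", C = "TTGGGACCG")))
  for (cs in cases) {
    tr <- ape::read.tree(text = cs$tree)
    aln <- codon_alignment(cs$seqs)
    ll <- tree_log_likelihood(aln, tr, model)
    expect_equal(ll, enumeration_loglik(aln, tr, model),
                 tolerance = 1e-8)
  }
})

test_that("single tip on a zero-length branch gives log root frequency", {
  # two identical tips at distance ~0: site likelihood -> rho_c
  model <- yn98_model(2, 0.5, matrix(0.25, 3, 4))
  tr <- ape::read.tree(text = "(A:1e-6,B:1e-6);")
  aln <- codon_alignment(c(A = "ATG", B = "ATG"))
  ll <- tree_log_likelihood(aln, tr, model)
  expect_equal(ll, log(model$root_freqs[["ATG"]]), tolerance = 1e-3)
})

test_that("all-gap columns contribute exactly zero log-likelihood", {
  model <- yn98_model(2, 0.4, matrix(0.25, 3, 4))
  tr <- tree3()
  a1 <- codon_alignment(c(A = "AAATTT", B = "AAGTTA", C = "CAATTG"))
  a2 <- codon_alignment(c(A = "AAATTT---", B = "AAGTTA---",
                          C = "CAATTG---"))
  expect_equal(tree_log_likelihood(a2, tr, model),
               tree_log_likelihood(a1, tr, model), tolerance = 1e-12)
})

test_that("likelihood is invariant to child order at a node", {
  model <- yn98_model(2, 0.4, matrix(0.25, 3, 4))
  aln <- codon_alignment(c(A = "AAATTT", B = "AAGTTA", C = "CAATTG"))
  t1 <- ape::read.tree(text = "((A:0.2,B:0.3):0.15,C:0.4);")
  t2 <- ape::read.tree(text = "(C:0.4,(B:0.3,A:0.2):0.15);")
  expect_equal(tree_log_likelihood(aln, t1, model),
               tree_log_likelihood(aln, t2, model), tolerance = 1e-10)
})

test_that("pulley principle holds at stationarity and fails away from it", {
  th <- matrix(c(0.3, 0.2, 0.2, 0.3,
                 0.25, 0.25, 0.25, 0.25,
                 0.2, 0.3, 0.3, 0.2), 3, 4, byrow = TRUE)
  aln <- codon_alignment(c(A = "AAATTTCCGGAT", B = "AAGTTACCGGAC",
                           C = "CAATTGCGGGAT"))
  # slide the root along the branch between the AB clade and C
  t1 <- ape::read.tree(text = "((A:0.2,B:0.3):0.10,C:0.30);")
  t2 <- ape::read.tree(text = "((A:0.2,B:0.3):0.25,C:0.15);")
  stat <- yn98_model(2, 0.4, th)             # rho = theta
  nonstat <- yn98_model(2, 0.4, th,
                        rho = matrix(0.25, 3, 4))
  expect_equal(tree_log_likelihood(aln, t1, stat),
               tree_log_likelihood(aln, t2, stat), tolerance = 1e-8)
  expect_gt(abs(tree_log_likelihood(aln, t1, nonstat) -
                  tree_log_likelihood(aln, t2, nonstat)), 1e-4)
})

test_that("identical sequences drive branch lengths to the lower bound", {
  tr <- tree3()
  aln <- codon_alignment(c(A = strrep("ATGCCC", 10),
                           B = strrep("ATGCCC", 10),
                           C = strrep("ATGCCC", 10)))
  fit <- fit_model(aln, tr, control = list(root_freqs = "observed",
                                           max_rounds = 2L, tol = 1e-4))
  expect_true(all(fit$tree$edge.length < 1e-4))
})

test_that("fitting recovers generating kappa and omega", {
  set.seed(21)
  tr <- ape::read.tree(text = paste0(
    "(((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1):0.05,(E:0.15,F:0.15):0.1);"))
  cfg <- sim_config(tr, kappa = 2, omega = 0.3, n_codons = 2000,
                    seed = 77L)
  sim <- simulate_alignment(cfg)
  fit <- quick_fit(sim$alignment, tr)
  expect_lt(abs(fit$model$kappa - 2), 0.3)
  expect_lt(abs(fit$model$omega - 0.3), 0.05)
  # re-evaluating at the fitted point reproduces the stored value
  ll <- tree_log_likelihood(sim$alignment, fit$tree, fit$model)
  expect_equal(ll, fit$loglik, tolerance = 1e-6)
  # optimization never ends below its start
  expect_gte(fit$loglik, fit$loglik_init)
})

test_that("node posteriors normalize and match brute-force Bayes", {
  # 3-taxon, 1 site: posterior at the root by direct enumeration
  th <- matrix(0.25, 3, 4)
  model <- yn98_model(2, 0.4, th,
                      rho = matrix(c(0.4, 0.2, 0.2, 0.2,
                                     0.25, 0.25, 0.25, 0.25,
                                     0.25, 0.25, 0.25, 0.25),
                                   3, 4, byrow = TRUE))
  tr <- tree3()
  aln <- codon_alignment(c(A = "AAA", B = "AAG", C = "CAA"))
  fit <- list(struct = condnds:::.tree_struct(tr),
              model = model)
  fit$prep <- condnds:::.prepare_data(aln, fit$struct)
  class(fit) <- "codon_fit"
  pd <- posterior_node_distributions(fit)
  for (p in pd$posteriors)
    expect_lt(max(abs(colSums(p) - 1)), 1e-10)
  dec <- condnds:::.decompose_generator(model$Q, model$pi)
  P <- function(t) condnds:::.transition_prob(dec, t)
  Pa <- P(0.2); Pb <- P(0.3); Pin <- P(0.15); Pc <- P(0.4)
  s <- aln$states
  rho <- model$root_freqs
  # root = ancestor of all three; x = internal node above A,B
  joint_root <- vapply(1:61, function(r) {
    rho[r] * Pc[r, s["C", 1]] *
      sum(vapply(1:61, function(x) Pin[r, x] * Pa[x, s["A", 1]] *
                   Pb[x, s["B", 1]], numeric(1L)))
  }, numeric(1L))
  root_post <- joint_root / sum(joint_root)
  expect_equal(unname(pd$posteriors[[pd$root]][, 1]), root_post,
               tolerance = 1e-9)

  # star-like dominance: identical ungapped tips put the posterior mode
  # on the observed codon at the root
  aln2 <- codon_alignment(c(A = "GGG", B = "GGG", C = "GGG"))
  fit2 <- list(struct = condnds:::.tree_struct(tr), model = model)
  fit2$prep <- condnds:::.prepare_data(aln2, fit2$struct)
  class(fit2) <- "codon_fit"
  pd2 <- posterior_node_distributions(fit2)
  expect_equal(which.max(pd2$posteriors[[pd2$root]][, 1]),
               match("GGG", genetic_code()$codons))
})
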