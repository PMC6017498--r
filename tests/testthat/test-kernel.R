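test_that("neural response equals hand-enumerated window frequencies", {
  r <- neural_response("ACGU", 2)
  expect_equal(r$n_windows, 3L)
  expect_equal(sort(r$entries),
               sort(c(AC = 1 / 3, CG = 1 / 3, GU = 1 / 3)))
  r2 <- neural_response("ACAC", 2)
  expect_equal(sort(r2$entries), sort(c(CA = 1 / 3, AC = 2 / 3)))
  expect_equal(neural_response("AAAA", 1)$entries, c(A = 1))
  expect_error(neural_response("ACG", 4), "shorter")
})

test_that("neural response matches the brute-force window oracle on random sequences", {
  set.seed(21)
  for (alpha in list(rpi_alphabet("rna4"), rpi_alphabet("protein20"))) {
    for (i in 1:40) {
      len <- sample(2:12, 1)
      s <- random_string(alpha, len)
      size <- sample(seq_len(min(len, 4L)), 1)
      got <- neural_response(s, size)$entries
      want <- oracle_response(s, size)
      expect_equal(got[order(names(got))], want[order(names(want))])
      expect_equal(sum(got), 1)  # windows each contribute 1/n_windows
    }
  }
})

test_that("raw second-layer kernel carries the uniform-measure factor", {
  f1 <- neural_response("A", 1)
  expect_equal(k2_raw(f1, f1, 4), 1 / 4)
  g1 <- neural_response("C", 1)
  expect_equal(k2_raw(f1, g1, 4), 0)
  f <- neural_response("ACAC", 2)
  g <- neural_response("CACA", 2)
  expect_equal(k2_raw(f, g, 4), (1 / 16) * (4 / 9))
  expect_error(k2_raw(f, f1, 4), "sizes differ")
})

test_that("correlation normalization yields cosine similarity with unit self-kernel", {
  f <- neural_response("ACAC", 2)
  g <- neural_response("CACA", 2)
  expect_equal(k2_normalized(f, g, 4), 0.8, tolerance = 1e-12)
  expect_equal(k2_normalized(g, f, 4), k2_normalized(f, g, 4))
  expect_equal(k2_normalized(neural_response("AAAA", 1),
                             neural_response("CCCC", 1), 4), 0)
  # the uniform-measure factor cancels: alphabet size is irrelevant
  expect_equal(k2_normalized(f, g, 4), k2_normalized(f, g, 20))
  # self-kernel is 1 for arbitrary sequences
  set.seed(31)
  for (i in 1:20) {
    s <- random_string(rpi_alphabet("protein20"), sample(3:40, 1))
    r <- neural_response(s, sample(1:3, 1))
    expect_equal(k2_normalized(r, r, 20), 1, tolerance = 1e-12)
  }
})

test_that("normalized kernel equals the dense cosine oracle", {
  set.seed(41)
  # RNA side: template spaces up to 4^6 = 4096
  for (i in 1:30) {
    size <- sample(1:3, 1)
    s1 <- random_string(rpi_alphabet("rna4"), sample(size:14, 1))
    s2 <- random_string(rpi_alphabet("rna4"), sample(size:14, 1))
    got <- k2_normalized(neural_response(s1, size),
                         neural_response(s2, size), 4)
    expect_equal(got, oracle_cosine(s1, s2, size, rpi_alphabet("rna4")))
    expect_gte(got, 0); expect_lte(got, 1)
  }
  # protein side at size 2 (20^2 = 400 templates)
  for (i in 1:10) {
    s1 <- random_string(rpi_alphabet("protein20"), 12)
    s2 <- random_string(rpi_alphabet("protein20"), 12)
    expect_equal(
      k2_normalized(neural_response(s1, 2), neural_response(s2, 2), 20),
      oracle_cosine(s1, s2, 2, rpi_alphabet("protein20"))
    )
  }
})

test_that("kernel depends only on the window-count profile; size 1 is composition cosine", {
  # same k-mer multiset, different sequences -> kernel exactly 1
  f <- neural_response("ACGU", 1)
  g <- neural_response("UGCA", 1)
  expect_equal(k2_normalized(f, g, 4), 1)
  # closed form at size 1: cosine of residue-composition vectors
  set.seed(5)
  for (i in 1:10) {
    s1 <- random_string(rpi_alphabet("rna4"), sample(5:30, 1))
    s2 <- random_string(rpi_alphabet("rna4"), sample(5:30, 1))
    comp <- function(s) vapply(rpi_alphabet("rna4"), function(a)
      lengths(regmatches(s, gregexpr(a, s, fixed = TRUE))), numeric(1))
    c1 <- comp(s1); c2 <- comp(s2)
    expect_equal(
      k2_normalized(neural_response(s1, 1), neural_response(s2, 1), 4),
      sum(c1 * c2) / sqrt(sum(c1^2) * sum(c2^2))
    )
  }
})

test_that("tensor-product pair kernel multiplies the two sequence kernels", {
  r1 <- "ACGUACGUAA"; p1 <- "MKVLAWQRST"
  r2 <- "GGCAUUCGAA"; p2 <- "MKVLAWQRSA"
  expect_equal(pair_kernel(r1, p1, r1, p1, k = 2, l = 3), 1)
  kr <- k2_normalized(neural_response(r1, 3), neural_response(r2, 3), 4)
  kp <- k2_normalized(neural_response(p1, 2), neural_response(p2, 2), 20)
  expect_equal(pair_kernel(r1, p1, r2, p2, k = 2, l = 3), kr * kp)
  # reduced alphabet route reduces the proteins before k-mer extraction
  kp7 <- k2_normalized(neural_response(reduce_protein(p1), 2),
                       neural_response(reduce_protein(p2), 2), 7)
  expect_equal(pair_kernel(r1, p1, r2, p2, k = 2, l = 3,
                           alphabet = "reduced7g"), kr * kp7)
})

test_that("Gram assembly is symmetric, unit-diagonal, PSD, and matches the scalar kernel", {
  sim <- simulate_rpi_data(n_pairs = 12, seed = 13)
  G <- rpi_gram(sim$pairs, sim$proteins, sim$rnas, k = 2, l = 3)
  expect_equal(dim(G), c(12L, 12L))
  expect_identical(G, t(G))
  expect_equal(unname(diag(G)), rep(1, 12))
  # dual route: matrix assembly vs the scalar pair_kernel path
  for (i in c(1, 4, 9)) for (j in c(2, 7, 12)) {
    expect_equal(
      G[i, j],
      pair_kernel(sim$rnas[sim$pairs$rna_id[i]],
                  sim$proteins[sim$pairs$protein_id[i]],
                  sim$rnas[sim$pairs$rna_id[j]],
                  sim$proteins[sim$pairs$protein_id[j]], k = 2, l = 3),
      tolerance = 1e-12
    )
  }
  # PSD within tolerance on a larger random pair set
  sim2 <- simulate_rpi_data(n_pairs = 50, seed = 17, signal_rate = 0.5)
  G2 <- rpi_gram(sim2$pairs, sim2$proteins, sim2$rnas, k = 2, l = 4)
  expect_gte(min(eigen(G2, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8 * 50)
  # pairs sharing a sequence reuse its response: identical rows give 1
  pairs_dup <- data.frame(protein_id = c("P0001", "P0001"),
                          rna_id = c("R0001", "R0002"))
  Gd <- rpi_gram(pairs_dup, sim$proteins, sim$rnas, k = 2, l = 3)
  expect_equal(Gd[1, 2],
               k2_normalized(neural_response(sim$rnas[["R0001"]], 3),
                             neural_response(sim$rnas[["R0002"]], 3), 4))
})

test_that("under-length sequences are a hard error naming the offenders", {
  prot <- c(pshort = "MK", pok = "MKVLAWQRST")
  rna <- c(rok = "ACGUACGU")
  pairs <- data.frame(protein_id = c("pshort", "pok"),
                      rna_id = c("rok", "rok"))
  expect_error(rpi_gram(pairs, prot, rna, k = 3, l = 2), "pshort")
})
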