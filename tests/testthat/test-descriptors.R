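test_that("Molfile parsing strips hydrogens and annotates the graph", {
  g <- parse_molfile(furan_molfile())
  expect_equal(nrow(g$atoms), 5L)
  expect_equal(nrow(g$bonds), 5L)
  expect_true(all(g$atoms$in_ring))
  expect_true(all(g$bonds$in_ring))
  # independent ring check: every edge of a single cycle lies on it
  expect_true(all(g$atoms$degree == 2L))

  # ethane with explicit hydrogens collapses to 2 atoms / 1 bond, no ring
  eth <- parse_molfile(make_molfile(
    c("C", "C", "H", "H", "H", "H", "H", "H"),
    data.frame(i = c(1, 1, 1, 1, 2, 2, 2), j = c(2, 3, 4, 5, 6, 7, 8),
               order = 1), name = "ethane"))
  expect_equal(nrow(eth$atoms), 2L)
  expect_equal(nrow(eth$bonds), 1L)
  expect_false(any(eth$bonds$in_ring))

  # N-methylacetamide: exactly one amide-flagged bond (C(=O)-N)
  nma <- parse_molfile(make_molfile(
    c("C", "C", "O", "N", "C"),
    data.frame(i = c(1, 2, 2, 4), j = c(2, 3, 4, 5), order = c(1, 2, 1, 1)),
    name = "N-methylacetamide"))
  expect_equal(sum(nma$bonds$amide), 1L)
  am <- nma$bonds[nma$bonds$amide, ]
  expect_setequal(c(am$i, am$j), c(2L, 4L))
})

test_that("Molfile contract violations raise errors", {
  bad <- c("x", "", "", "not a counts line")
  expect_error(parse_molfile(bad), "counts line")
  disc <- make_molfile(c("C", "C", "C"),
                       data.frame(i = 1, j = 2, order = 1))
  expect_error(parse_molfile(disc), "disconnected")
})

test_that("rotatable bond number excludes ring, amide and terminal bonds", {
  fx <- fixture_molecules()
  expect_equal(rotatable_bond_count(fx[["2-nonene"]]), 5L)
  expect_equal(rotatable_bond_count(fx[["adamantane"]]), 0L)
  expect_equal(rotatable_bond_count(fx[["n-butane"]]), 1L)
  # amide bond in N-methylacetamide is excluded even though non-terminal
  expect_equal(rotatable_bond_count(fx[["N-methylacetamide"]]), 0L)
  # fully cyclic graphs have RBN 0
  expect_equal(rotatable_bond_count(fx[["cyclohexane"]]), 0L)
  expect_equal(rotatable_bond_count(fx[["furan"]]), 0L)
})

test_that("kappa indices reproduce closed-form and hand-computed values", {
  fx <- fixture_molecules()
  # linear all-sp3 chain: kappa1 = A, kappa2 = A-1, so PHI = A-1 exactly
  k <- kappa_indices(fx[["n-hexane"]])
  expect_equal(k$A, 6L)
  expect_equal(k$P1, 5L)
  expect_equal(k$P2, 4)
  expect_equal(k$phi, 5)
  # cyclohexane: A=6, P1=P2=6, alpha=0 -> direct arithmetic oracle
  expect_equal(kappa_indices(fx[["cyclohexane"]])$phi,
               (6 * 25 / 36) * (5 * 16 / 36) / 6, tolerance = 1e-12)
  expect_equal(kier_phi(fx[["cyclohexane"]]), 1.54)
  expect_error(kappa_indices(molecule_graph(c("C", "C"),
               data.frame(i = 1, j = 2, order = 1))), "fewer than 3")
})

test_that("flexibility index matches printed values for study compounds", {
  fx <- fixture_molecules()
  expect_equal(kier_phi(fx[["furan"]]), 0.55)
  expect_equal(kier_phi(fx[["2-nonene"]]), 7.52, tolerance = 0.011)
  expect_equal(kier_phi(fx[["1,8-nonadiene"]]), 7.05)
})

test_that("linear alkanes follow the PHI = A - 1 closed form", {
  for (A in 3:12) {
    g <- molecule_graph(rep("C", A),
                        data.frame(i = 1:(A - 1), j = 2:A, order = 1))
    expect_equal(kappa_indices(g)$phi, A - 1, tolerance = 1e-12)
  }
})

test_that("closing a ring strictly decreases PHI at fixed atom count", {
  for (A in c(4, 6, 8, 10)) {
    chain <- molecule_graph(rep("C", A),
                            data.frame(i = 1:(A - 1), j = 2:A, order = 1))
    ring <- molecule_graph(rep("C", A),
                           data.frame(i = c(1:(A - 1), A),
                                      j = c(2:A, 1), order = 1))
    expect_lt(kappa_indices(ring)$phi, kappa_indices(chain)$phi)
  }
})

test_that("P2 equals brute-force 2-path enumeration on random graphs", {
  set.seed(4242)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    # random tree plus a few extra edges keeps the graph connected
    parent <- vapply(2:n, function(v) sample(v - 1, 1), integer(1))
    extra <- sample(0:3, 1)
    edges <- cbind(parent, 2:n)
    for (e in seq_len(extra)) edges <- rbind(edges, sort(sample(n, 2)))
    edges <- unique(edges)
    g <- molecule_graph(rep("C", n),
                        data.frame(i = edges[, 1], j = edges[, 2],
                                   order = 1))
    # brute force: count paths u-v-w over all ordered triples, halve
    adj <- matrix(FALSE, n, n)
    adj[edges] <- TRUE
    adj <- adj | t(adj)
    cnt <- 0
    for (u in 1:n) for (v in 1:n) for (w in 1:n)
      if (u != v && v != w && u != w && adj[u, v] && adj[v, w])
        cnt <- cnt + 1
    expect_equal(kappa_indices(g)$P2, cnt / 2)
  }
})
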