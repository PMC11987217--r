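test_that("meta-path names parse into typed node sequences", {
  mp <- parse_metapath("DPS")
  expect_equal(mp$node_sequence, c("domain", "protein", "disease"))
  expect_equal(mp$length, 2L)
  expect_error(parse_metapath("DDS"), "no edge type D-D")
  expect_error(parse_metapath("SPD"), "must start at domain")
  expect_error(parse_metapath("DS"), "length at least 2")
  expect_error(parse_metapath("DpS"), "outside D/P/S")
})

test_that("the canonical registry reproduces the printed path counts", {
  expect_equal(length(canonical_registry(5)), 27L)
  expect_equal(length(canonical_registry(4)), 17L)
  expect_equal(length(canonical_registry(3)), 6L)
  expect_equal(length(canonical_registry(2)), 2L)
  expect_equal(length(canonical_registry(6)), 37L)

  reg <- canonical_registry(6)
  lens <- vapply(reg$paths, `[[`, 0L, "length")
  expect_equal(unname(table(lens)), array(c(2L, 4L, 11L, 10L, 10L)))
  nms <- vapply(reg$paths, `[[`, "", "name")
  expect_false(anyDuplicated(nms) > 0)
  expect_false(anyDuplicated(reg$ids) > 0)
  expect_equal(reg$ids[1:2], c("C1", "C2"))
  expect_equal(nms[1:2], c("DPS", "DSS"))
  expect_error(canonical_registry(7), "between 2 and 6")
})

test_that("commuting matrices count walks on hand-checked toys", {
  # single chain d1 - p1 - p2 - s1
  net <- toy_net(dp = "d1 p1", pp = "p1 p2", ps = "p2 s1")
  expect_equal(commuting_matrix(net, "DPPS")["d1", "s1"], 1)

  # two parallel protein routes
  net2 <- toy_net(dp = c("d1 p1", "d1 p2"), ps = c("p1 s1", "p2 s1"))
  expect_equal(commuting_matrix(net2, "DPS")["d1", "s1"], 2)

  # similarity hop completes the path
  net3 <- toy_net(dp = "d1 p1", ps = "p1 s1", ss = "s1 s2")
  expect_equal(commuting_matrix(net3, "DPSS")["d1", "s2"], 1)

  # empty network: all-zero matrices for every registry path
  net0 <- toy_net(dp = "d1 p1", ps = "p9 s1")  # d1 disconnected from s1
  net0$adj$DP["d1", "p1"] <- 0
  for (p in canonical_registry(6)$paths)
    expect_equal(Matrix::nnzero(commuting_matrix(net0, p)), 0L)
})

test_that("chain products are associative and reversal transposes", {
  net <- random_net(7)
  for (nm in c("DPPSS", "DSPDS", "DPSPPS")) {
    mp <- parse_metapath(nm)
    seqs <- mp$node_sequence
    mats <- lapply(seq_len(length(seqs) - 1L),
                   function(k) adjacency(net, seqs[k], seqs[k + 1L]))
    left <- Reduce(`%*%`, mats)
    right <- Reduce(`%*%`, mats, right = TRUE)
    expect_equal(as.matrix(left), as.matrix(right))
    expect_equal(as.matrix(commuting_matrix(net, mp)), as.matrix(left),
                 ignore_attr = TRUE)
    # reversed node sequence: product of reversed transposes = transpose
    rev_mats <- rev(lapply(mats, Matrix::t))
    expect_equal(as.matrix(Reduce(`%*%`, rev_mats)),
                 t(as.matrix(left)), ignore_attr = TRUE)
  }
})

test_that("adding an edge never decreases a commuting-matrix entry", {
  reg <- canonical_registry(5)
  for (s in 1:5) {
    net <- random_net(s)
    before <- lapply(reg$paths, function(p) commuting_matrix(net, p))
    net2 <- net
    # add one P-S edge absent so far
    zero <- which(as.matrix(net2$adj$PS) == 0, arr.ind = TRUE)
    if (!nrow(zero)) next
    net2$adj$PS[zero[1L, 1L], zero[1L, 2L]] <- 1
    for (k in seq_along(reg$paths)) {
      after <- commuting_matrix(net2, reg$paths[[k]])
      expect_true(all(as.matrix(after) - as.matrix(before[[k]]) >= 0))
    }
  }
})

test_that("a pair's own reference edge cannot feed DSS through self-similarity", {
  # d1-s1 reference edge plus s1 similar to s2; DSS(d1, s1) would need
  # the s1-s1 self-loop, which the build forces to zero
  net <- toy_net(dp = "d1 p1", ps = "p1 s1", ss = "s1 s2", ds = "d1 s1")
  expect_equal(commuting_matrix(net, "DSS")["d1", "s1"], 0)
  expect_equal(commuting_matrix(net, "DSS")["d1", "s2"], 1)
})

test_that("explicit walk enumeration matches hand-counted toys and guards size", {
  net <- toy_net(dp = "d1 p1", ps = "p1 s1", ss = "s1 s2")
  expect_equal(brute_force_path_count(net, "DPSS", "d1", "s2"), 1L)
  # a direct p1-s2 link adds no DPSS walk to s2 unless an S-S hop completes it
  net2 <- toy_net(dp = "d1 p1", ps = c("p1 s1", "p1 s2"), ss = "s1 s2")
  expect_equal(brute_force_path_count(net2, "DPSS", "d1", "s2"), 1L)
  expect_equal(brute_force_path_count(net2, "DPSS", "d1", "s1"), 1L)
  expect_equal(brute_force_path_count(net, "DPS", "d1", "s2"), 0L)

  big <- structure(list(
    nodes = list(domain = sprintf("d%d", 1:200),
                 protein = sprintf("p%d", 1:200),
                 disease = sprintf("s%d", 1:200)),
    adj = list()), class = "hetnet")
  expect_error(brute_force_path_count(big, "DPPPS", "d1", "s1"),
               "too large")
})

test_that("registry and commuting matrices export to JSON/TSV", {
  reg <- canonical_registry(3)
  f <- withr::local_tempfile(fileext = ".json")
  write_registry_json(reg, f)
  recs <- jsonlite::read_json(f)
  expect_equal(length(recs), 6L)
  expect_equal(recs[[1L]]$name, "DPS")

  net <- toy_net(dp = c("d1 p1", "d1 p2"), ps = c("p1 s1", "p2 s1"))
  cm <- commuting_matrix(net, "DPS")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_commuting_matrix(cm, tf)
  df <- read.table(tf, header = TRUE, sep = "\t")
  expect_equal(df$count[df$domain_id == "d1" & df$disease_id == "s1"], 2)
})
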