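test_that("random-walk normalization turns rows into proportions", {
  m <- Matrix::Matrix(rbind(c(1, 3), c(0, 0), c(2, 2)), sparse = TRUE)
  r <- rw_normalize(m)
  expect_equal(as.numeric(r[1, ]), c(0.25, 0.75))
  expect_equal(as.numeric(r[2, ]), c(0, 0))       # zero row stays zero
  expect_equal(as.numeric(r[3, ]), c(0.5, 0.5))
  m4 <- Matrix::Matrix(matrix(2, 1, 4), sparse = TRUE)
  expect_equal(as.numeric(rw_normalize(m4)), rep(0.25, 4))
  expect_equal(sum(rw_normalize(m4)), 1)
})

test_that("every nonzero row of every normalized registry matrix sums to 1", {
  reg <- canonical_registry(6)
  for (s in c(3, 11)) {
    net <- random_net(s)
    for (p in reg$paths) {
      r <- rw_normalize(commuting_matrix(net, p))
      rs <- Matrix::rowSums(r)
      expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
      expect_true(all(r@x >= 0 & r@x <= 1))
    }
  }
})

test_that("feature tables have registry-order columns, counts then RW", {
  net <- random_net(5)
  pairs <- expand.grid(domain = net$nodes$domain[1:2],
                       disease = net$nodes$disease[1:2],
                       stringsAsFactors = FALSE)
  reg <- canonical_registry(5)
  ft2 <- assemble_features(net, pairs, reg, mode = "counts+rw")
  expect_equal(ncol(ft2) - 2L, 54L)
  ft1 <- assemble_features(net, pairs, reg, mode = "counts")
  expect_equal(ncol(ft1) - 2L, 27L)
  # counts block is a prefix shared by both modes
  expect_equal(names(ft2)[3:29], names(ft1)[3:29])
  expect_true(all(grepl("_count$", names(ft1)[-(1:2)])))
  expect_true(all(grepl("_rw$", names(ft2)[31:56])))

  empty <- assemble_features(net, pairs[0, ], reg, mode = "counts+rw")
  expect_equal(nrow(empty), 0L)
  expect_equal(ncol(empty), 56L)

  expect_error(assemble_features(net, data.frame(domain = "nope",
                                                 disease = net$nodes$disease[1]),
                                 reg),
               "unknown label")
})

test_that("RW features equal counts over the full-universe row sum", {
  net <- random_net(9)
  pairs <- expand.grid(domain = net$nodes$domain,
                       disease = net$nodes$disease,
                       stringsAsFactors = FALSE)
  reg <- canonical_registry(3)
  ft <- assemble_features(net, pairs, reg, mode = "counts+rw")
  for (p in reg$paths) {
    cm <- commuting_matrix(net, p)
    full <- as.matrix(rw_normalize(cm))    # explicitly materialized
    got <- ft[[paste0(p$name, "_rw")]]
    expect_equal(got, full[cbind(match(ft$domain_id, rownames(full)),
                                 match(ft$disease_id, colnames(full)))])
  }
})

test_that("features are pair-local: permuting pairs permutes rows", {
  net <- random_net(13)
  pairs <- expand.grid(domain = net$nodes$domain,
                       disease = net$nodes$disease,
                       stringsAsFactors = FALSE)[1:6, ]
  reg <- canonical_registry(4)
  ft <- assemble_features(net, pairs, reg, mode = "counts+rw")
  perm <- c(4, 2, 6, 1, 3, 5)
  ft_perm <- assemble_features(net, pairs[perm, ], reg, mode = "counts+rw")
  expect_equal(as.data.frame(ft_perm), as.data.frame(ft)[perm, ],
               ignore_attr = TRUE)
})

test_that("a domain reaching exactly one disease gets RW exactly 1", {
  net <- toy_net(dp = "d1 p1", ps = "p1 s1", ss = "s1 s2")
  ft <- assemble_features(net, data.frame(domain = "d1", disease = "s1"),
                          canonical_registry(2), mode = "counts+rw")
  expect_equal(ft$DPS_rw, 1)
})

test_that("presets give the published column counts", {
  net <- random_net(21)
  pairs <- data.frame(domain = net$nodes$domain[1],
                      disease = net$nodes$disease[1])
  widths <- c("TF1" = 6L, "TF2" = 17L, "TF3" = 27L, "TF4" = 37L,
              "Feature-I" = 27L, "Feature-II" = 54L)
  for (preset in names(widths)) {
    ft <- feature_set(net, pairs, preset)
    expect_equal(ncol(ft) - 2L, unname(widths[[preset]]),
                 info = preset)
    expect_equal(attr(ft, "feature_set_name"), preset)
  }
  # Feature-I columns are a prefix of Feature-II columns
  f1 <- feature_set(net, pairs, "Feature-I")
  f2 <- feature_set(net, pairs, "Feature-II")
  expect_equal(names(f1), names(f2)[seq_len(ncol(f1))])
  expect_error(feature_set(net, pairs, "TF9"))
})

test_that("strict masking removes only the pair's own reference edge", {
  # d1-s1 is a reference edge; DPDS picks it up through any protein of d1
  net <- toy_net(dp = c("d1 p1", "d2 p2"), ps = c("p1 s1", "p2 s2"),
                 ss = "s1 s2", ds = c("d1 s1", "d2 s2"))
  reg <- canonical_registry(3)
  pairs <- data.frame(domain = c("d1", "d1"), disease = c("s1", "s2"))

  paper <- leakage_controlled_network(net, pairs[0, ], "paper")
  strict <- leakage_controlled_network(net, pairs[0, ], "strict")
  fp <- assemble_features(paper, pairs, reg, mode = "counts+rw")
  fs <- assemble_features(strict, pairs, reg, mode = "counts+rw")

  # own-edge pair: DPDS = #proteins(d1) * DS(d1,s1) = 1 in paper mode, 0 strict
  expect_equal(fp$DPDS_count[1], 1)
  expect_equal(fs$DPDS_count[1], 0)
  # pair without a direct edge: identical in the two modes
  expect_equal(unlist(fp[2, -(1:2)]), unlist(fs[2, -(1:2)]))
})

test_that("strict per-pair rows are bit-identical to a full recomputation", {
  net <- random_net(31)
  # give every domain a reference edge to make masking bite
  ds_pairs <- data.frame(domain = net$nodes$domain,
                         disease = net$nodes$disease[1])
  net$adj$DS[cbind(seq_along(net$nodes$domain), 1L)] <- 1
  reg <- canonical_registry(5)
  strict <- leakage_controlled_network(net, ds_pairs[0, ], "strict")
  fs <- assemble_features(strict, ds_pairs, reg, mode = "counts+rw")
  for (i in seq_len(min(3L, nrow(ds_pairs)))) {
    net_i <- remove_domain_disease_edges(net, ds_pairs[i, ])
    ref <- assemble_features(net_i, ds_pairs[i, ], reg, mode = "counts+rw")
    expect_equal(unlist(fs[i, -(1:2)]), unlist(ref[1, -(1:2)]))
  }
})

test_that("feature tables write CSV plus a provenance sidecar", {
  net <- toy_net(dp = "d1 p1", ps = "p1 s1")
  ft <- feature_set(net, data.frame(domain = "d1", disease = "s1"), "TF1")
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, f)
  back <- read.csv(f)
  expect_equal(ncol(back), 8L)   # 2 ids + 6 features
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$feature_set_name, "TF1")
  expect_equal(meta$n_feature_columns, 6L)
})
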