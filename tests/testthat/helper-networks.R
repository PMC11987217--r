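# Shared fixtures: small hand-built networks and seedable random networks.

# Build a network from named character-vector edge lists, e.g.
#   toy_net(dp = c("d1 p1", "d1 p2"), ps = c("p1 s1"))
# Unmentioned layers are empty; node universes are whatever the edges name.
toy_net <- function(dp = character(0), pp = character(0), ps = character(0),
                    ss = character(0), ds = character(0)) {
  sp <- function(x) {
    if (!length(x)) return(list(character(0), character(0)))
    parts <- strsplit(x, " +")
    list(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
  }
  a <- sp(dp); b <- sp(pp); c_ <- sp(ps); d <- sp(ss); e <- sp(ds)
  build_hetnet(list(
    edge_table(a[[1]], a[[2]], "domain", "protein"),
    edge_table(b[[1]], b[[2]], "protein", "protein"),
    edge_table(c_[[1]], c_[[2]], "protein", "disease"),
    edge_table(d[[1]], d[[2]], "disease", "disease"),
    edge_table(e[[1]], e[[2]], "domain", "disease")
  ))
}

# Random small network with every layer drawn Bernoulli(density).
# All nodes are guaranteed to appear (self-free square layers, full
# universes) by adding each node through at least one layer when drawn
# edges miss it; isolated nodes are simply absent, which is fine for the
# oracle tests as long as labels come from the built network.
random_net <- function(seed, n_max = 7L, density = NULL) {
  set.seed(seed)
  nd <- sample(3:n_max, 1L); np <- sample(3:n_max, 1L); ns <- sample(3:n_max, 1L)
  density <- density %||% runif(1L, 0.15, 0.4)
  dom <- paste0("d", seq_len(nd)); pro <- paste0("p", seq_len(np))
  dis <- paste0("s", seq_len(ns))
  draw <- function(rows, cols) {
    hits <- which(matrix(runif(length(rows) * length(cols)),
                         length(rows)) < density, arr.ind = TRUE)
    list(rows[hits[, 1L]], cols[hits[, 2L]])
  }
  a <- draw(dom, pro); b <- draw(pro, pro); c_ <- draw(pro, dis)
  d <- draw(dis, dis); e <- draw(dom, dis)
  build_hetnet(list(
    edge_table(a[[1]], a[[2]], "domain", "protein"),
    edge_table(b[[1]], b[[2]], "protein", "protein"),
    edge_table(c_[[1]], c_[[2]], "protein", "disease"),
    edge_table(d[[1]], d[[2]], "disease", "disease"),
    edge_table(e[[1]], e[[2]], "domain", "disease")
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pairwise Mann-Whitney statistic: fraction of (positive, negative) score
# pairs correctly ordered, ties counted half.  Independent oracle for AUC.
mann_whitney_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}
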