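test_that("input scores sum neighbour means", {
  expect_equal(input_scores(star_net(4), rep(1, 5))$score, c(4, 1, 1, 1, 1))
  # degree-0 node scores 0
  adj <- matrix(0L, 3, 3); adj[1, 2] <- adj[2, 1] <- 1L
  expect_equal(input_scores(as_dw_network(adj), c(1, 1, 1))$score, c(1, 1, 0))
  # path 1-2-3 with means (1, 1, 7)
  expect_equal(input_scores(path_net(3), c(1, 1, 7))$score, c(1, 8, 1))
  expect_error(input_scores(path_net(3), c(1, 1)), "per node")
})

test_that("correlation scores are a structure-free input-score proxy", {
  # all-constant series: undefined correlations contribute 0
  block <- make_block(matrix(5, 20, 3))
  expect_equal(correlation_scores(block)$score, c(0, 0, 0))
  # a duplicated series contributes exactly its mean (cor = 1)
  set.seed(9)
  a <- rnorm(100); c_ <- rnorm(100)
  block <- make_block(cbind(a, a + 2, c_))
  sc <- correlation_scores(block)$score
  expect_equal(sc[1] - cor(a, c_) * mean(c_), mean(a + 2))
  # independent mean-zero noise: scores near zero
  block <- make_block(matrix(rnorm(3000), ncol = 3))
  expect_true(all(abs(correlation_scores(block)$score) < 0.2))
})

test_that("each selection rule matches its definition", {
  thr <- classification_thresholds(1, 4, 7)[["lower"]]
  # path 1-2-3, node 3 transitioned; means (1, 1, 7), R = (1, 8, 1)
  samples <- matrix(rep(c(1, 1, 7), each = 30), ncol = 3)
  block <- make_block(samples, state_at_relax = c(1, 1, 7))
  net <- path_net(3)
  sel <- function(kind, n = 5, side = "lower", ...)
    select_node_set(kind, block, net = net, initial_side = side,
                    threshold = thr, n = n, ...)
  expect_identical(sel("all"), 1:3)
  expect_identical(sel("lower_state"), 1:2)
  expect_identical(sel("upper_state"), 3L)
  # top available node by R_i: node 2 (node 3 is unavailable)
  expect_identical(sel("high_input", n = 1), 2L)
  expect_identical(sel("low_input", n = 1), 1L)
  # n >= #available: the full available set
  expect_identical(sel("high_input", n = 5), 1:2)
  # random: n nodes from all nodes, deterministic given seed
  r1 <- sel("random", n = 2, seed = 3)
  expect_identical(r1, sel("random", n = 2, seed = 3))
  expect_length(r1, 2)
  expect_true(all(r1 %in% 1:3))
  expect_error(select_node_set("bogus", block, threshold = thr), "arg")
  expect_error(sel("lower_half", side = "upper"), "upper-start")
})

test_that("upper_state is empty before any node transitions", {
  block <- make_block(matrix(1, 20, 4), state_at_relax = rep(1, 4))
  expect_identical(
    select_node_set("upper_state", block, initial_side = "lower",
                    threshold = 2.268),
    integer(0))
})

test_that("lower_half keeps available lower-state nodes strictly below the median R_i", {
  # star: hub 1 with 4 leaves, all lower; R = (4, 1, 1, 1, 1)
  net <- star_net(4)
  block <- make_block(matrix(1, 30, 5), state_at_relax = rep(1, 5))
  sel <- select_node_set("lower_half", block, net = net,
                         initial_side = "lower", threshold = 2.268)
  expect_identical(sel, integer(0)) # median(4,1,1,1,1) = 1; none strictly below
  # distinct scores: exactly the lower half
  net4 <- path_net(4) # R over constant means 1: degrees (1, 2, 2, 1)
  block4 <- make_block(matrix(1, 30, 4), state_at_relax = rep(1, 4))
  sel4 <- select_node_set("lower_half", block4, net = net4,
                          initial_side = "lower", threshold = 2.268)
  expect_identical(sel4, c(1L, 4L)) # degree-1 ends below median 1.5
})

test_that("large_sd and large_correlation rank availability-restricted nodes", {
  thr <- 2.268
  set.seed(12)
  base <- matrix(rnorm(200 * 4, sd = 0.01), ncol = 4)
  base[, 2] <- base[, 2] * 50               # node 2: largest s.d.
  base <- base + 1
  base[, 4] <- base[, 4] + 6                # node 4 transitioned
  block <- make_block(base, state_at_relax = base[1, ])
  expect_identical(
    select_node_set("large_sd", block, initial_side = "lower",
                    threshold = thr, n = 1),
    2L)
  # node 4 has large s.d. too but is unavailable
  base2 <- base; base2[, 4] <- base2[, 4] * 100
  block2 <- make_block(base2, state_at_relax = base[1, ])
  expect_identical(
    select_node_set("large_sd", block2, initial_side = "lower",
                    threshold = thr, n = 1),
    2L)
  sel_lc <- select_node_set("large_correlation", block, initial_side = "lower",
                            threshold = thr, n = 2)
  expect_length(sel_lc, 2)
  expect_true(all(sel_lc %in% 1:3))
})

test_that("selection properties: sizes, disjointness, degree ranking, ties", {
  thr <- classification_thresholds(1, 4, 7)[["lower"]]
  net <- generate_er(20, 5, seed = 10)
  set.seed(44)
  samples <- matrix(rnorm(100 * net$N, mean = 1, sd = 0.05), ncol = net$N)
  block <- make_block(samples, state_at_relax = samples[1, ])
  for (kind in c("high_input", "low_input", "random", "large_correlation",
                 "large_sd")) {
    sel <- select_node_set(kind, block, net = net, initial_side = "lower",
                           threshold = thr, n = 5, seed = 2)
    expect_length(sel, 5)
    expect_identical(anyDuplicated(sel), 0L)
    expect_true(all(sel >= 1 & sel <= net$N))
  }
  hi <- select_node_set("high_input", block, net = net,
                        initial_side = "lower", threshold = thr, n = 5)
  lo <- select_node_set("low_input", block, net = net,
                        initial_side = "lower", threshold = thr, n = 5)
  expect_length(intersect(hi, lo), 0) # N = 20 >= 2n
  # with near-constant means, R_i ranking is degree ranking: star hub wins
  star <- star_net(6)
  sblock <- make_block(matrix(1, 50, 7), state_at_relax = rep(1, 7))
  expect_identical(
    select_node_set("high_input", sblock, net = star,
                    initial_side = "lower", threshold = thr, n = 1),
    1L)
  # ties broken by lowest node index: leaves all tie at R = 1
  expect_identical(
    select_node_set("low_input", sblock, net = star,
                    initial_side = "lower", threshold = thr, n = 3),
    2:4)
})

test_that("membership_samples restricts scores without touching signals", {
  set.seed(77)
  m <- matrix(1 + rnorm(100 * 3, sd = 0.001), ncol = 3)
  m[1:10, 1] <- 1 + (m[1:10, 1] - 1) * 30    # node 1: big early s.d.
  m[11:100, 3] <- 1 + (m[11:100, 3] - 1) * 400 # node 3: big overall s.d.
  block <- make_block(m, state_at_relax = m[1, ])
  full <- select_node_set("large_sd", block, initial_side = "lower",
                          threshold = 2.268, n = 1)
  first10 <- select_node_set("large_sd", block, initial_side = "lower",
                             threshold = 2.268, n = 1,
                             membership_samples = 10)
  expect_identical(full, 3L)
  expect_identical(first10, 1L)
})
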