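test_that("rank-sum test gives the exact worked p-value and direction", {
  ht <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ht$p_value, 0.1)
  expect_equal(ht$direction, -1)
  expect_false(ht$degenerate)
  same <- rank_sum_test(rep(2, 5), rep(2, 7))
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum type-I error is controlled at nominal level", {
  set.seed(61)
  rej <- mean(replicate(1000, {
    rank_sum_test(rnorm(500), rnorm(500))$p_value <= 0.05
  }))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("BH adjustment matches the direct step-up computation", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.5))
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.2, 6)), rep(0.2, 6))
  set.seed(62)
  for (rep in 1:1000) {
    p <- runif(sample(1:25, 1))
    expect_equal(fdr_adjust(p), bh_direct(p), tolerance = 1e-12)
  }
  # family larger than the tested subset inflates the adjustment
  expect_equal(fdr_adjust(c(0.01, 0.02), n_family = 10),
               p.adjust(c(0.01, 0.02), "BH", n = 10))
  expect_true(all(fdr_adjust(c(0.01, 0.5)) >= c(0.01, 0.5)))
})

test_that("the dissimilarity gate passes no cell under the null", {
  set.seed(63)
  diss <- expand.grid(trial = 1:80, band = c("theta", "gamma"),
                      window = 1:5, stringsAsFactors = FALSE)
  diss$condition <- rep(c("face", "ketch"), length.out = nrow(diss))
  diss$score <- rnorm(nrow(diss))
  gate <- gate_by_dissimilarity(diss, c("face", "ketch"))
  expect_equal(nrow(gate), 10)
  expect_false(any(gate$pass))
  expect_true(all(gate$p_adj >= gate$p_raw))
})

test_that("a missing condition in a cell is skipped with a warning", {
  diss <- expand.grid(trial = 1:20, band = "gamma", window = 1:2,
                      stringsAsFactors = FALSE)
  diss$condition <- "face"
  diss$condition[diss$window == 1] <-
    rep(c("face", "ketch"), 10)
  diss$score <- rnorm(nrow(diss))
  expect_warning(gate <- gate_by_dissimilarity(diss, c("face", "ketch")),
                 "missing")
  expect_equal(nrow(gate), 1)
})

# simulate a measure table with iid values (global null) or a planted
# location shift of the star-vs-chain signature in one cell
simulate_measures <- function(n_per, delta = 0, seed = 1) {
  set.seed(seed)
  cells <- expand.grid(band = c("theta", "gamma"), window = 1:5,
                       stringsAsFactors = FALSE)
  rows <- list()
  for (k in seq_len(nrow(cells))) {
    for (cond in c("face", "ketch")) {
      shift <- if (cells$band[k] == "gamma" && cells$window[k] == 2 &&
                     cond == "face") delta else 0
      rows[[length(rows) + 1]] <- data.frame(
        trial = seq_len(n_per) +
          (cond == "ketch") * n_per,
        condition = cond, subject = "s01",
        band = cells$band[k], window = cells$window[k],
        diameter = rnorm(n_per, 0.5 - shift, 0.1),
        leaf_fraction = rnorm(n_per, 0.6 + shift, 0.1),
        max_bc = rnorm(n_per, 0.7, 0.1),
        max_degree = rnorm(n_per, 0.4 + shift, 0.1),
        tree_hierarchy = rnorm(n_per, 0.5, 0.1),
        mst_pli = rnorm(n_per, 0.7, 0.1))
    }
  }
  list(global = do.call(rbind, rows), nodal = NULL)
}

all_pass_gate <- function() {
  gate <- expand.grid(band = c("theta", "gamma"), window = 1:5,
                      stringsAsFactors = FALSE)
  gate$p_raw <- 0.001
  gate$p_adj <- 0.01
  gate$direction <- 1
  gate$pass <- TRUE
  gate
}

test_that("selection flags at most the nominal fraction under the null", {
  flagged <- replicate(100, {
    meas <- simulate_measures(30, delta = 0,
                              seed = sample.int(1e6, 1))
    sel <- select_features(meas, all_pass_gate(), c("face", "ketch"))
    mean(sel$significant)
  })
  # BH under the global null: expected flagged fraction well below alpha
  expect_lte(mean(flagged), 0.05 + 2 * sd(flagged) / sqrt(100))
})

test_that("selection recovers a planted star-ward shift with direction", {
  meas <- simulate_measures(150, delta = 0.15, seed = 64)
  sel <- select_features(meas, all_pass_gate(), c("face", "ketch"))
  hit <- function(msr) sel[sel$measure == msr & sel$band == "gamma" &
                             sel$window == 2, ]
  expect_true(hit("leaf_fraction")$significant)
  expect_equal(hit("leaf_fraction")$direction, 1)
  expect_true(hit("max_degree")$significant)
  expect_equal(hit("max_degree")$direction, 1)
  expect_true(hit("diameter")$significant)
  expect_equal(hit("diameter")$direction, -1)
  # invariance to trial ordering
  perm <- sample(nrow(meas$global))
  meas2 <- list(global = meas$global[perm, ], nodal = NULL)
  sel2 <- select_features(meas2, all_pass_gate(), c("face", "ketch"))
  ord <- function(s) s[order(s$measure, s$band, s$window), ]
  expect_equal(ord(as.data.frame(sel2))$p_raw,
               ord(as.data.frame(sel))$p_raw)
})

test_that("an empty gate yields an empty selection table", {
  meas <- simulate_measures(20, seed = 65)
  gate <- all_pass_gate()
  gate$pass <- FALSE
  sel <- select_features(meas, gate, c("face", "ketch"))
  expect_equal(nrow(sel), 0)
  expect_equal(nrow(feature_manifest(sel)), 0)
})
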