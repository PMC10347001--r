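test_that("contact detection thresholds at 20 N with a closed boundary", {
  expect_identical(detect_contact(c(25, 10, 20, 0, 19.999)),
                   c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_error(detect_contact(c(5, -1)), "non-negative")
})

test_that("raising the threshold never adds contact samples", {
  set.seed(3)
  g <- abs(rnorm(500, 100, 80))
  prev <- detect_contact(g, 5)
  for (thr in c(10, 20, 50, 150)) {
    cur <- detect_contact(g, thr)
    expect_true(all(prev | !cur))  # cur is a subset of prev
    prev <- cur
  }
})

test_that("the phase machine reads heel strikes and toe-offs correctly", {
  # hand-built tracks for one cycle starting mid-SW-R, then a full cycle:
  # left stance throughout SW-R; right strikes (SU-RHS), left toe-off (SW-L),
  # left strikes (SU-LHS), right toe-off (SW-R)
  left  <- c(1, 1, 1, 1, 1, 0, 0, 0, 1, 1, 1) == 1
  right <- c(0, 0, 1, 1, 1, 1, 1, 1, 1, 0, 0) == 1
  ph <- as.character(derive_phases(left, right))
  expect_identical(ph, c("SW-R", "SW-R", "SU-RHS", "SU-RHS", "SU-RHS",
                         "SW-L", "SW-L", "SW-L", "SU-LHS", "SW-R", "SW-R"))
  # left loaded alone -> right swing
  expect_true(all(ph[left & !right] == "SW-R"))
})

test_that("pre-event samples take the predecessor of the first event's phase", {
  # first event is a left toe-off (SW-L) at sample 4 -> backward extension SU-RHS
  left  <- c(1, 1, 1, 0, 0, 0) == 1
  right <- c(1, 1, 1, 1, 1, 1) == 1
  ph <- as.character(derive_phases(left, right))
  expect_identical(ph, c("SU-RHS", "SU-RHS", "SU-RHS", "SW-L", "SW-L", "SW-L"))
})

test_that("degenerate contact tracks are rejected or flagged", {
  expect_error(derive_phases(rep(TRUE, 10), rep(TRUE, 10)), "anchor")
  expect_error(derive_phases(rep(TRUE, 5), rep(TRUE, 6)), "length")
  # both feet airborne: warned, machine keeps running on the edge events
  left  <- c(1, 1, 0, 0, 0, 1) == 1
  right <- c(1, 1, 1, 0, 1, 1) == 1
  msgs <- capture_warnings(ph <- derive_phases(left, right))
  expect_true(any(grepl("both feet", msgs)))
  expect_identical(as.character(ph),
                   c("SU-RHS", "SU-RHS", "SW-L", "SW-R", "SU-RHS", "SU-LHS"))
})

test_that("derived labels follow the strict cyclic order on walking data", {
  rec <- simulate_recording(clean_config(), 1, 1.2, seed = 9)
  ph <- as.character(label_recording(rec)$phase)
  chg <- which(ph[-1] != head(ph, -1))
  expect_true(all(ph[chg + 1] == next_phase(ph[chg])))
})

test_that("one-hot encoding matches the fixed phase order and round-trips", {
  m <- one_hot(gait_phases())
  expect_equal(unname(m), diag(4))
  expect_equal(as.numeric(one_hot("SU-RHS")), c(1, 0, 0, 0))
  expect_equal(as.numeric(one_hot("SW-R")), c(0, 0, 0, 1))
  expect_identical(decode_phase(m), gait_phases())
  expect_identical(decode_phase(c(0.1, 0.7, 0.1, 0.1)), "SW-L")
  expect_warning(tie <- decode_phase(c(0.4, 0.4, 0.1, 0.1)), "tie")
  expect_identical(tie, "SU-RHS")
  expect_error(one_hot("SU-XYZ"), "unknown")
})

test_that("next_phase walks the cycle and has order four", {
  expect_identical(next_phase("SU-RHS"), "SW-L")
  expect_identical(next_phase("SW-R"), "SU-RHS")
  p <- "SU-LHS"
  for (k in 1:4) p <- next_phase(p)
  expect_identical(p, "SU-LHS")
})

test_that("windows are labeled by their final sample", {
  phases <- rep(c("SW-L", "SU-LHS"), each = 30)
  expect_identical(label_window(5, 20, phases), "SW-L")     # homogeneous
  expect_identical(label_window(15, 20, phases), "SU-LHS")  # straddling
  expect_error(label_window(50, 20, phases), "outside")
  # majority alternative
  expect_identical(label_window(15, 20, phases, rule = "majority"), "SW-L")
})

test_that("stride-1 window labels change exactly at the track's transitions", {
  rec <- simulate_recording(clean_config(), 1, 1.5, seed = 3)
  w <- segment_windows(rec, stride = 1)
  lab <- as.character(w$label)
  ph <- as.character(rec$phase)
  # window i ends at sample i+19; its label must equal that sample's phase
  expect_identical(lab, ph[w$start + 19L])
  expected_changes <- sum(ph[-(1:20)] != ph[20:(length(ph) - 1)])
  expect_identical(sum(lab[-1] != head(lab, -1)), expected_changes)
})
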