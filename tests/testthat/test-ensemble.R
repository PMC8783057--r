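make_class_trace <- function(E_levels, on, n = 200, dt = 0.04, id = "m1") {
  # on: list of c(start, end) 0-based half-open bound intervals
  tot <- rep(200, n)
  E <- rep(0.5, n)
  for (iv in on) {
    idx <- (iv[1] + 1):iv[2]
    tot[idx] <- 800
    E[idx] <- E_levels[[as.character(iv[1])]] %||% 0.5
  }
  polfret::time_trace(DD = tot * (1 - E), DA = tot * E, frame_dt = dt,
                      molecule_id = id)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("frame classification bins partition [0, 1] with upper-bin edges", {
  dt <- 0.04
  E_seq <- c(0.1, 0.4, 0.6, 0.9, 0.3, 0.53, 0.8, 0, 1)
  tot <- rep(800, length(E_seq))
  tr <- time_trace(DD = tot * (1 - E_seq), DA = tot * E_seq, frame_dt = dt,
                   molecule_id = "m1")
  ev <- detect_events(tr, threshold = 500, min_duration = 0)
  cls <- classify_frames(tr, ev)
  expect_equal(as.character(cls),
               c("donor_only", "open", "closed", "high_unassigned",
                 "open", "closed", "high_unassigned", # edges go up
                 "donor_only", "high_unassigned"))

  # every defined E* maps to exactly one class (partition property),
  # out-of-range values clamp to the nearest bin
  grid <- c(seq(-0.2, 1.2, by = 0.01))
  idx <- polfret:::classify_E(grid)
  expect_true(all(idx %in% 2:5))
  expect_equal(polfret:::classify_E(c(-0.5, 1.5)), c(2L, 5L))

  # below the intensity threshold frames are unbound regardless of E*
  tot2 <- c(800, 200, 800)
  E2 <- c(0.6, 0.6, 0.6)
  tr2 <- time_trace(DD = tot2 * (1 - E2), DA = tot2 * E2, frame_dt = dt,
                    molecule_id = "m1")
  ev2 <- detect_events(tr2, threshold = 500, min_duration = 0,
                       bridge_gap = 0)
  cls2 <- classify_frames(tr2, ev2)
  expect_equal(as.character(cls2), c("closed", "unbound", "closed"))
})

test_that("binding extent is the covered fraction of the window", {
  tr <- make_class_trace(list(), list(), n = 250)
  ev <- detect_events(tr, threshold = 500)
  expect_equal(binding_extent(tr, ev, c(0, 10)), 0)

  tr2 <- make_class_trace(list(`0` = 0.6), list(c(0, 250)), n = 250)
  ev2 <- detect_events(tr2, threshold = 500)
  expect_equal(binding_extent(tr2, ev2, c(0, 10)), 1)

  # 3 s bound of a 10 s window
  tr3 <- make_class_trace(list(`50` = 0.6), list(c(50, 125)), n = 250)
  ev3 <- detect_events(tr3, threshold = 500)
  expect_equal(binding_extent(tr3, ev3, c(0, 10)), 0.3)
  expect_error(binding_extent(tr3, ev3, c(5, 5)), "window")
})

test_that("heat-map sorting and group c removal follow the two-pass rule", {
  dt <- 0.04
  n <- 1000 # 40 s at 25 Hz; t_add at 20 s
  mk <- function(id, on) {
    lv <- lapply(on, function(iv) 0.6)
    names(lv) <- vapply(on, function(iv) as.character(iv[1]), character(1))
    make_class_trace(lv, on, n = n, id = id)
  }
  traces <- list(
    low = mk("low", list()),                        # no binding: group c
    hi  = mk("hi", list(c(100, 450), c(520, 980))), # heavy post binding
    mid = mk("mid", list(c(100, 450), c(520, 600))) # light post binding
  )
  traces <- structure(traces, class = "trace_set", frame_dt = dt, t_add = 20)
  ev <- detect_events_set(traces)
  hm <- build_heatmap(traces, ev, t_add = 20, low_binding_cutoff = 0.05,
                      rules = group_rules(tail_window = 10))
  expect_equal(unname(hm$group_labels["low"]), "c_low_binding")
  expect_equal(nrow(hm$matrix), 2L)
  # least post-addition binding at the bottom (first row)
  expect_equal(hm$sort_order, c("mid", "hi"))
  expect_error(build_heatmap(traces, ev, t_add = 100), "t_add")

  # sorting is a pure function of extents: permutation invariance
  hm2 <- build_heatmap(traces[c(3, 1, 2)], ev, t_add = 20,
                       rules = group_rules(tail_window = 10))
  expect_equal(hm2$sort_order, hm$sort_order)
  expect_equal(hm2$matrix, hm$matrix)
})

test_that("group classification separates persistent, bright and dark", {
  dt <- 0.04
  n <- 1000 # t_add 20 s, trace end 40 s
  persistent <- make_class_trace(list(`0` = 0.45), list(c(0, 1000)),
                                 n = n, id = "pers")
  bright <- make_class_trace(list(`100` = 0.4, `510` = 0.62),
                             list(c(100, 450), c(510, 610)), n = n,
                             id = "bright")
  dark <- make_class_trace(list(`100` = 0.4), list(c(100, 450)), n = n,
                           id = "dark")
  traces <- structure(list(pers = persistent, bright = bright, dark = dark),
                      class = "trace_set", frame_dt = dt, t_add = 20)
  evs <- lapply(traces, detect_events, threshold = 500)
  g <- classify_groups(traces, evs, t_add = 20,
                       rules = group_rules(tail_window = 10))
  expect_equal(unname(g[c("pers", "bright", "dark")]),
               c("a_persistent", "b_bright", "b_dark"))
  expect_error(classify_groups(traces, evs, t_add = NA), "t_add")
})

test_that("synthetic group-c fractions match the generator within binomial error", {
  # 30% forced non-binders, all-dual labelling so visibility equals
  # ground-truth occupancy; binding fast enough that low pre-addition
  # extent by chance is rare
  sch <- kinetic_scheme(n_max = 0, t_add = 72, binding_rate = 0.1)
  n_mol <- 150
  ex <- simulate_experiment(sch, phys_dual(), n_mol, 120,
                            contaminant_fraction = 0,
                            no_binding_fraction = 0.30, seed = 17)
  ev <- detect_events_set(ex$traces)
  hm <- build_heatmap(ex$traces, ev, t_add = 72, low_binding_cutoff = 0.05)
  frac_c <- mean(hm$group_labels == "c_low_binding")

  # (i) binomial agreement with the generator's non-binder fraction
  expect_lt(abs(frac_c - 0.30), 3 * sqrt(0.3 * 0.7 / n_mol) + 0.03)

  # (ii) exact agreement with the ground-truth pre-addition occupancy rule
  truly_c <- vapply(ex$paths, function(p) {
    pre <- pmin(p$t_end, 72) - pmin(p$t_start, 72)
    sum(pre[p$state != "unbound"]) / 72 < 0.05
  }, logical(1))
  agree <- mean((hm$group_labels == "c_low_binding") == truly_c)
  expect_gt(agree, 0.95)
})

test_that("post-synchronised FRET histograms populate and mark empties", {
  dt <- 0.04
  tr <- make_class_trace(list(`50` = 0.65), list(c(50, 150)), n = 300,
                         id = "m1")
  traces <- structure(list(m1 = tr), class = "trace_set", frame_dt = dt)
  ev <- detect_events_set(traces)
  h <- postsync_fret_histogram(ev, traces, begins_closed_only = TRUE)
  expect_false(h$empty)
  # all mass in the single E* column containing 0.65
  colmass <- colSums(h$counts)
  expect_equal(sum(colmass > 0), 1L)
  expect_equal(sum(h$counts), 100L)

  h0 <- postsync_fret_histogram(ev, traces, begins_closed_only = TRUE,
                                complement = TRUE)
  expect_true(h0$empty)
})

test_that("ensemble FRET relaxes from closed toward open after extension", {
  sch <- kinetic_scheme(n_max = 5, t_add = 0, dntp_wait_rate = 50,
                        incorporation_rates = c(A = 3.2, C = 3.2,
                                                G = 3.2, T = 3.2))
  ex <- sim_dual(sch, 120, 40, seed = 19,
                 phys = phys_dual(red_laser_window = 0))
  ev <- detect_events_set(ex$traces)
  h <- postsync_fret_histogram(ev, ex$traces, begins_closed_only = TRUE,
                               t_bins = seq(0, 4, by = 0.04))
  expect_gt(h$n_events, 20)
  Emids <- (h$E_bins[-1] + h$E_bins[-length(h$E_bins)]) / 2
  colmean <- function(rows) {
    m <- colSums(h$counts[rows, , drop = FALSE])
    sum(Emids * m) / sum(m)
  }
  early <- colmean(1:5)            # first 0.2 s: dominated by closed
  late <- colmean(66:90)           # 2.6-3.6 s: mostly returned to open
  expect_gt(early, 0.55)
  expect_lt(late, 0.5)
})

test_that("heat-map rendering is colour-stable with the fixed palette", {
  m <- matrix(0L, 2, 10)
  m[2, ] <- 3L
  hm <- structure(list(matrix = m, sort_order = c("a", "b"),
                       group_labels = c(a = "b_dark", b = "b_bright"),
                       t_add = 0.2, frame_dt = 0.04),
                  class = "ensemble_matrix")
  cols <- render_heatmap(hm, draw = FALSE)
  expect_true(all(cols[1, ] == "#FFFFFF")) # unbound row all white
  expect_true(all(cols[2, ] == "#B2182B")) # closed row solid red
  cols2 <- render_heatmap(hm, draw = FALSE)
  expect_identical(cols, cols2)

  e <- structure(list(matrix = matrix(integer(0), 0, 0)),
                 class = "ensemble_matrix")
  expect_error(render_heatmap(e), "empty")
})
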