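brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cst <- sum(cost[cbind(seq_len(n), p)])
    if (cst < best_cost) { best_cost <- cst; best <- p }
  }
  list(assignment = best, cost = best_cost)
}

test_that("the assignment solver is exact against brute-force enumeration", {
  set.seed(601)
  for (i in 1:60) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n, n)
    a <- solve_assignment(cost)
    bf <- brute_force_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]), bf$cost,
                 tolerance = 1e-12)
  }
})

test_that("greedy matching agrees with the exact solver on non-degenerate gates", {
  set.seed(602)
  for (i in 1:20) {
    # well-separated points: nearest-neighbour structure is unambiguous
    n <- 5
    truth <- matrix(runif(n * 3, 0, 1e5), n, 3)
    jitter <- truth + matrix(rnorm(n * 3, 0, 50), n, 3)
    cost <- as.matrix(dist(rbind(truth, jitter)))[1:n, n + 1:n]^2
    expect_equal(solve_assignment(cost), greedy_assignment(cost))
  }
})

test_that("stationary emitters link into clean full-length tracks", {
  sp <- do.call(rbind, lapply(1:10, function(f)
    make_spots(frame = f, z = c(2000, 2000), y = c(2000, 5000),
               x = c(2000, 2000))))
  tracks <- link_tracks(sp, max_displacement = 800, max_gap = 2)
  expect_length(tracks, 2)
  expect_true(all(vapply(tracks, function(t) nrow(t$spots), integer(1)) == 10))
  expect_true(all(vapply(tracks, function(t) length(t$flags) == 0,
                         logical(1))))
})

test_that("a single missed frame is bridged as a gap", {
  frames <- setdiff(1:8, 5)
  sp <- do.call(rbind, lapply(frames, function(f)
    make_spots(frame = f, z = 2000, y = 2000, x = 2000 + 50 * f)))
  tracks <- link_tracks(sp, max_displacement = 800, max_gap = 2)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$gap_frames, 5)
})

test_that("crossing trajectories are flagged merged/split", {
  sp <- do.call(rbind, lapply(1:9, function(f)
    make_spots(frame = f, z = c(2000, 2000), y = c(2000, 2000),
               x = c(1000 + 300 * f, 4000 - 300 * f))))
  tracks <- link_tracks(sp, max_displacement = 800, max_gap = 2)
  flagged <- vapply(tracks, function(t)
    any(c("merged", "split") %in% t$flags), logical(1))
  expect_gte(sum(flagged), 2)
})

test_that("no identity switches for well-separated emitters", {
  set.seed(603)
  n_em <- 60
  start <- cbind(runif(n_em, 0, 3e5), runif(n_em, 0, 3e5),
                 runif(n_em, 0, 3e5))
  # enforce >= 5x the gate between every pair
  keep <- rep(TRUE, n_em)
  d <- as.matrix(dist(start))
  for (i in 2:n_em) if (any(d[i, seq_len(i - 1)] < 5 * 800)) keep[i] <- FALSE
  start <- start[keep, , drop = FALSE]
  n_em <- nrow(start)
  sp <- do.call(rbind, lapply(1:10, function(f) {
    pos <- start + matrix(rnorm(n_em * 3, 0, 100), n_em, 3)
    make_spots(frame = f, z = pos[, 1], y = pos[, 2], x = pos[, 3])
  }))
  tracks <- link_tracks(sp, max_displacement = 800, max_gap = 2)
  expect_length(tracks, n_em)
  lens <- vapply(tracks, function(t) nrow(t$spots), integer(1))
  expect_true(all(lens == 10))
  # every track stays near its starting emitter: zero switches
  for (tr in tracks) {
    spread <- max(dist(tr$spots[, c("z", "y", "x")]))
    expect_lt(spread, 2000)
  }
})

test_that("filter_valid partitions tracks and applies every rule", {
  g <- acq_geometry(n_volumes = 20, volume_shape = c(24, 80, 80))
  mid <- c(3000, 4000, 4000)
  mk <- function(frames, z = mid[1], y = mid[2], x = mid[3],
                 flags = character(0), accepted = TRUE) {
    s <- do.call(rbind, lapply(frames, function(f)
      make_spots(frame = f, z = z, y = y, x = x, accepted = accepted)))
    list(track_id = 1L, spots = s, gap_frames = integer(0), flags = flags,
         class_label = "unclassified")
  }
  tracks <- list(
    mk(3:8),                                  # valid
    mk(1:5),                                  # touches series start
    mk(15:20),                                # touches series end
    mk(1:20),                                 # persistent
    mk(3:8, y = 1200),                        # near border (1.2 um)
    mk(3:4),                                  # too short
    mk(3:8, flags = "merged"),                # merged
    mk(3:8, accepted = FALSE))                # below significance
  out <- filter_valid(tracks, g, border_margin = 1500, min_frames = 3)
  expect_length(out$valid, 1)
  expect_length(out$persistent, 1)
  expect_length(out$rejected, 6)
  expect_equal(length(out$valid) + length(out$persistent) +
                 length(out$rejected), length(tracks))
  reasons <- lapply(out$rejected, `[[`, "rejection_reasons")
  expect_true(any(vapply(reasons, function(r)
    "touches_series_start" %in% r, logical(1))))
  expect_true(any(vapply(reasons, function(r)
    "touches_series_end" %in% r, logical(1))))
  expect_true(any(vapply(reasons, function(r)
    "near_border" %in% r, logical(1))))
  expect_true(any(vapply(reasons, function(r)
    "too_short" %in% r, logical(1))))
  expect_true(any(vapply(reasons, function(r)
    "merged" %in% r, logical(1))))
  expect_true(any(vapply(reasons, function(r)
    "below_significance" %in% r, logical(1))))
})

test_that("classification separates mobile point spots from bright static clusters", {
  g <- acq_geometry(n_volumes = 20, volume_shape = c(24, 80, 80))
  psf <- psf_model(geom = g)
  set.seed(604)
  mobile_track <- function(id) {
    pos <- cbind(3000 + cumsum(rnorm(10, 0, 120)),
                 4000 + cumsum(rnorm(10, 0, 120)),
                 4000 + cumsum(rnorm(10, 0, 120)))
    list(track_id = id,
         spots = make_spots(1:10, pos[, 1], pos[, 2], pos[, 3],
                            amplitude = 500, sigma_xy = psf$sigma_xy),
         gap_frames = integer(0), flags = character(0),
         class_label = "unclassified")
  }
  static_cluster <- function(id) {
    list(track_id = id,
         spots = make_spots(1:10, 3000 + rnorm(10, 0, 15),
                            4000 + rnorm(10, 0, 15),
                            4000 + rnorm(10, 0, 15),
                            amplitude = 2500,
                            sigma_xy = 1.6 * psf$sigma_xy),
         gap_frames = integer(0), flags = character(0),
         class_label = "unclassified")
  }
  dim_static <- function(id) {
    list(track_id = id,
         spots = make_spots(1:10, 3000 + rnorm(10, 0, 15),
                            4000 + rnorm(10, 0, 15),
                            4000 + rnorm(10, 0, 15),
                            amplitude = 400, sigma_xy = psf$sigma_xy),
         gap_frames = integer(0), flags = character(0),
         class_label = "unclassified")
  }
  tracks <- classify_tracks(c(lapply(1:4, mobile_track),
                              list(static_cluster(5L), dim_static(6L))),
                            psf)
  labels <- vapply(tracks, `[[`, character(1), "class_label")
  expect_equal(labels, c("I", "I", "I", "I", "II", "unclassified"))
})
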