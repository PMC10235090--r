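walk_to <- function(times, secs, subs, class = "walk") {
  data.frame(time = times, section = secs, subsection = subs,
             class = rep_len(class, length(times)), stringsAsFactors = FALSE)
}

# straight start -> target trajectory on the default arena
straight_path <- function() {
  secs <- c(rep("stem_upper", 9), rep("stalk_ipsi", 10), rep("leaf_ipsi", 10))
  subs <- c(9:1, 1:10, 1:10)
  walk_to(seq_along(secs), secs, subs)
}

test_that("traverse_distance sums consecutive path distances", {
  a <- default_arena()
  expect_equal(traverse_distance(walk_to(numeric(0), character(0),
                                         integer(0)), a), 0)
  # out-and-back is twice the one-way distance
  out_back <- walk_to(c(1, 2), c("stalk_ipsi", "stem_upper"), c(10, 10))
  one_way <- path_distance(a, a$start, location("stalk_ipsi", 10))
  expect_equal(traverse_distance(out_back, a), 2 * one_way)
  expect_error(traverse_distance(walk_to(c(2, 1), rep("stem_upper", 2),
                                         c(5, 4)), a), "sorted")
})

test_that("traverse_distance agrees with pairwise oracle summation", {
  a <- default_arena()
  g <- oracle_midpoint_graph(a)
  set.seed(41)
  for (k in 1:50) {
    n <- sample(2:15, 1)
    locs <- replicate(n, random_location(a), simplify = FALSE)
    tr <- walk_to(seq_len(n),
                  vapply(locs, `[[`, character(1), "section"),
                  vapply(locs, `[[`, integer(1), "subsection"),
                  sample(c("walk", "search"), n, replace = TRUE))
    path <- c(list(a$start), locs)
    expected <- sum(vapply(seq_len(n), function(i)
      oracle_path_distance(g, path[[i]], path[[i + 1]]), numeric(1)))
    expect_equal(traverse_distance(tr, a), expected, tolerance = 1e-10)
    expected_search <- sum(vapply(which(tr$class == "search"), function(i)
      oracle_path_distance(g, path[[i]], path[[i + 1]]), numeric(1)))
    expect_equal(traverse_distance(tr, a, class_filter = "search"),
                 expected_search, tolerance = 1e-10)
  }
})

test_that("approach ratio anchors 0 at the start and 1 at the target", {
  expect_equal(approach_ratio(201, 201), 0)
  expect_equal(approach_ratio(0, 201), 1)
  expect_equal(approach_ratio(100.5, 201), 0.5)
  expect_equal(approach_ratio(300, 201), 0)  # moving farther clips to 0
  expect_error(approach_ratio(10, 0), "positive")
})

test_that("path metrics on straight and out-and-back walks", {
  a <- default_arena()
  tr1 <- trial_record(straight_path(), random_train(0),
                      trial_duration = 900)
  p1 <- path_metrics(tr1, a)
  expect_equal(p1$path_efficiency, 1)
  expect_equal(p1$approach, 1)
  expect_true(p1$found_target)
  expect_equal(p1$total_distance, start_distance(a))

  back <- straight_path()
  ret <- walk_to(30 + seq_len(nrow(back)),
                 c(rev(back$section)[-1], "stem_upper"),
                 c(rev(back$subsection)[-1], 10))
  tr2 <- trial_record(rbind(back, ret), random_train(0), trial_duration = 900)
  p2 <- path_metrics(tr2, a)
  expect_equal(p2$path_efficiency, 0.5)
  expect_equal(p2$approach, 1)

  expect_error(path_metrics(trial_record(straight_path()[0, ], random_train(0),
                                         trial_duration = 900), a),
               "excluded")
})

test_that("overall efficiency follows the formula with its conventions", {
  expect_equal(overall_efficiency(0, 100, 1), 0.5)
  expect_equal(overall_efficiency(0, 1000, 1), 1 / 3)
  expect_equal(overall_efficiency(0.3, 100, 0), 0)
  # frozen independent evaluation of 0.6 / log10(300)
  expect_equal(overall_efficiency(0.4, 210, 0.7), 0.2422165, tolerance = 1e-6)
  # denominator floor keeps very short walks finite and positive
  expect_equal(overall_efficiency(0, 1, 1), 10)
  expect_gt(overall_efficiency(0.5, 0.5, 1), 0)
  expect_error(overall_efficiency(0.1, 0, 1), "positive")
})

test_that("straight silent walk scores eff = 1 with the arena unit scale", {
  a <- default_arena()
  expect_equal(overall_efficiency(0, start_distance(a), 1,
                                  unit_scale = eff_unit_scale(a)), 1)
})

test_that("eff is monotone in its arguments", {
  dc <- seq(0, 0.9, by = 0.1)
  eff_dc <- vapply(dc, overall_efficiency, numeric(1),
                   total_distance = 300, approach = 0.8)
  expect_true(all(diff(eff_dc) < 0))
  d <- seq(50, 2000, by = 50)
  eff_d <- vapply(d, function(x) overall_efficiency(0.2, x, 0.8), numeric(1))
  expect_true(all(diff(eff_d) < 0))
  ap <- seq(0.05, 1, by = 0.05)
  eff_a <- vapply(ap, function(x) overall_efficiency(0.2, 300, x), numeric(1))
  expect_true(all(diff(eff_a) > 0))
})

test_that("trial metrics assemble into a tidy row and flag excluded trials", {
  a <- default_arena()
  tr <- trial_record(straight_path(), random_train(5, t_max = 60),
                     trial_duration = 300, male_id = "m1", repetition = 2)
  row <- compute_trial_metrics(tr, a)
  expect_equal(nrow(row), 1)
  expect_false(row$excluded)
  expect_true(row$found_target)
  expect_true(row$eff > 0 && row$duty_cycle >= 0)

  still <- trial_record(straight_path()[0, ], random_train(3),
                        trial_duration = 300)
  row2 <- compute_trial_metrics(still, a)
  expect_true(row2$excluded)
  expect_true(is.na(row2$eff))
  expect_false(is.na(row2$duty_cycle))  # signaling metrics still defined
})
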