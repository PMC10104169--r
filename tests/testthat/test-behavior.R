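# NOR scoring arithmetic: DI, concatenation, splits, screens.

test_that("the discrimination index follows its formula and is antisymmetric", {
  v <- visit_record(c("novel", "familiar"), c(0, 10), c(6, 13))
  sc <- discrimination_index(v)
  expect_equal(sc$di, 1 / 3)
  expect_equal(sc$total_exploration_s, 9)
  swapped <- visit_record(c("familiar", "novel"), c(0, 10), c(6, 13))
  expect_equal(discrimination_index(swapped)$di, -sc$di)
  eq <- visit_record(c("novel", "familiar"), c(0, 10), c(4, 14))
  expect_equal(discrimination_index(eq)$di, 0)
  only_novel <- visit_record("novel", 0, 5)
  expect_error(discrimination_index(only_novel), "each object class")
  expect_true(passes_di_screen(sc))
  expect_false(passes_di_screen(0.1))
})

test_that("visit records validate ordering and overlap", {
  expect_error(visit_record(c("a", "b"), c(0, 2), c(3, 4)), "overlap")
  expect_error(visit_record("a", 5, 5), "end > start")
  v <- visit_record(c("b", "a"), c(4, 0), c(6, 2))
  expect_equal(v$object, c("a", "b"))   # reordered by time
})

test_that("five-second concatenation uses the documented visit counts", {
  # [2, 2, 2]: two whole visits + 1 s of the third
  v <- visit_record(rep("novel", 3), c(0, 5, 10), c(2, 7, 12))
  ep <- concatenate_visits(v, 5)
  expect_equal(attr(ep, "n_visits"), 3)
  expect_equal(attr(ep, "total_s"), 5)
  expect_equal(sum(ep$end_s - ep$start_s), 5)
  expect_equal(ep$end_s[3], 11)          # third visit truncated to 1 s
  # [6]: single visit truncated to 5 s
  v2 <- visit_record("novel", 3, 9)
  ep2 <- concatenate_visits(v2, 5)
  expect_equal(attr(ep2, "n_visits"), 1)
  expect_equal(ep2$end_s - ep2$start_s, 5)
  # [1.2 x 4] = 4.8 s total: all used, flagged short
  v3 <- visit_record(rep("novel", 4), c(0, 2, 4, 6), c(1.2, 3.2, 5.2, 7.2))
  ep3 <- concatenate_visits(v3, 5)
  expect_true(attr(ep3, "short"))
  expect_equal(attr(ep3, "total_s"), 4.8, tolerance = 1e-9)
  # order = "last" accumulates backward, truncating the head
  ep4 <- concatenate_visits(v, 5, order = "last")
  expect_equal(attr(ep4, "n_visits"), 3)
  expect_equal(ep4$start_s[1], 1)        # first visit keeps only its tail
  # truncate = FALSE keeps the final visit whole
  ep5 <- concatenate_visits(v2, 5, truncate = FALSE)
  expect_equal(attr(ep5, "total_s"), 6)
})

test_that("early/late familiarization splits are disjoint and validated", {
  # total exactly 10 s: early and late partition the exploration exactly
  v <- visit_record(rep("left", 2), c(0, 20), c(5, 25))
  sp <- split_early_late(v)
  expect_equal(sum(sp$early$end_s - sp$early$start_s), 5)
  expect_equal(sum(sp$late$end_s - sp$late$start_s), 5)
  for (i in seq_len(nrow(sp$early))) {
    for (j in seq_len(nrow(sp$late))) {
      ov <- min(sp$early$end_s[i], sp$late$end_s[j]) -
        max(sp$early$start_s[i], sp$late$start_s[j])
      expect_lte(ov, 0)
    }
  }
  # < 10 s of familiarization is invalid
  short <- visit_record(rep("left", 3), c(0, 5, 10), c(3, 8, 13))
  expect_error(split_early_late(short), "invalid familiarization")
  # 12 visits totalling 30 s: early uses leading visits only, late trailing
  set.seed(101)
  starts <- seq(0, by = 10, length.out = 12)
  v12 <- visit_record(rep(c("left", "right"), 6), starts, starts + 2.5)
  sp12 <- split_early_late(v12)
  # manual accumulation: 2.5 + 2.5 = 5 exactly -> 2 visits each side
  expect_equal(attr(sp12$early, "n_visits"), 2)
  expect_equal(attr(sp12$late, "n_visits"), 2)
  expect_lt(max(sp12$early$end_s), min(sp12$late$start_s))
})

test_that("visit-epoch labeling produces one 5-s epoch per object class", {
  starts <- seq(0, by = 8, length.out = 9)
  objs <- c(rep("novel", 4), rep("familiar", 5))
  v <- visit_record(objs, starts, starts + 2)
  eps <- label_visit_epochs(v, "STM")
  expect_setequal(names(eps), c("novel", "familiar"))
  for (obj in names(eps)) {
    expect_equal(sum(eps[[obj]]$end_s - eps[[obj]]$start_s), 5)
    expect_false(attr(eps[[obj]], "short"))
  }
  # an object with only 3 s total is short-flagged
  v2 <- visit_record(c("novel", "familiar"), c(0, 10), c(3, 16))
  eps2 <- label_visit_epochs(v2, "LTM")
  expect_true(attr(eps2$novel, "short"))
  expect_equal(attr(eps2$novel, "total_s"), 3)
  # missing class warns
  expect_warning(label_visit_epochs(visit_record("novel", 0, 6), "STM"),
                 "familiar")
})

test_that("epochs from the generator schedule align with the ground truth", {
  vs <- data.frame(label = c("novel", "familiar", "novel", "familiar"),
                   start_s = c(2, 10, 18, 26), end_s = c(5, 14, 21, 30))
  ses <- gen_behavior_session(ground_truth(visit_schedule = vs, seed = 102))
  v <- visit_record(ses$recording$events$label,
                    ses$recording$events$onset_s,
                    ses$recording$events$offset_s)
  eps <- label_visit_epochs(v, "STM")
  expect_equal(eps$novel$start_s[1], 2)
  expect_equal(sum(eps$novel$end_s - eps$novel$start_s), 5)
  sc <- discrimination_index(v)
  expect_equal(sc$di, ((3 + 3) - (4 + 4)) / 14)
})
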