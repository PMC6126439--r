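ref2 <- data.frame(lesion = c("L1", "L2"),
                   x_mm = c(100, 180), y_mm = c(100, 140))

test_that("marks match by distance with the one-to-one nearest rule", {
  marks <- data.frame(reader = 1, mode = "U",
                      x_mm = c(103, 220, 178, 183),
                      y_mm = c(104, 220, 139, 141),
                      chi = c(3, 2, 4, 1))
  st <- match_marks(marks, ref2, tolerance_mm = 15)
  m <- st[st$label != "FN", ]
  expect_equal(m$label[1], "TP")          # 5 mm away
  expect_equal(m$label[2], "FP")          # 40+ mm from everything
  # two marks near L2: the nearer one (178,139; 2.2 mm) wins, the other is FP
  near <- st[!is.na(st$lesion) & st$lesion == "L2", ]
  expect_equal(nrow(near), 1L)
  expect_equal(near$chi, 4)
  expect_equal(sum(st$label == "FP"), 2L)
})

test_that("unmarked reference lesions become false negatives scored 0", {
  marks <- data.frame(reader = 1, mode = "MC", x_mm = 101, y_mm = 99, chi = 4)
  st <- match_marks(marks, ref2)
  fn <- st[st$label == "FN", ]
  expect_equal(fn$lesion, "L2")
  expect_equal(fn$chi, 0)
})

test_that("chi outside 1..4 is rejected", {
  marks <- data.frame(reader = 1, mode = "U", x_mm = 1, y_mm = 1, chi = 5)
  expect_error(match_marks(marks, ref2), "chi")
})

test_that("uniformly confident readers give flat detection statistics", {
  marks <- expand.grid(reader = 1:2, mode = c("U", "MC"))
  marks <- do.call(rbind, lapply(seq_len(nrow(marks)), function(i) {
    data.frame(reader = marks$reader[i], mode = marks$mode[i],
               x_mm = ref2$x_mm, y_mm = ref2$y_mm, chi = 4)
  }))
  st <- match_marks(marks, ref2)
  ds <- detection_summary(st)
  expect_true(all(ds$tp_rate$rate == 1))
  expect_true(all(unlist(ds$dchi) == 0))
  expect_equal(ds$wilcoxon$p.value, 1)
  expect_equal(unname(ds$fp_counts), c(0, 0))
})

test_that("a uniform MC improvement is detected by the signed-rank test", {
  refs <- data.frame(lesion = paste0("L", 1:8),
                     x_mm = seq(40, 250, length.out = 8),
                     y_mm = rep(100, 8))
  rows <- list()
  for (rd in 1:2) for (i in 1:8) {
    chi_u <- ((i + rd) %% 3) + 1
    rows[[length(rows) + 1]] <- data.frame(
      reader = rd, mode = "U", x_mm = refs$x_mm[i], y_mm = 100, chi = chi_u)
    rows[[length(rows) + 1]] <- data.frame(
      reader = rd, mode = "MC", x_mm = refs$x_mm[i], y_mm = 100,
      chi = min(chi_u + 1, 4))
  }
  st <- match_marks(do.call(rbind, rows), refs)
  ds <- detection_summary(st)
  expect_true(all(ds$dchi_sum >= 0))
  expect_lt(ds$wilcoxon$p.value, 0.05)
  expect_gt(ds$mean_chi[["MC"]], ds$mean_chi[["U"]])
})

test_that("a small constructed table reproduces hand-enumerated counts", {
  refs <- data.frame(lesion = c("A", "B", "C", "D"),
                     x_mm = c(50, 100, 150, 200), y_mm = rep(120, 4))
  marks <- rbind(
    data.frame(reader = 1, mode = "U", x_mm = c(50, 100, 290),
               y_mm = c(120, 120, 50), chi = c(2, 3, 1)),
    data.frame(reader = 1, mode = "MC", x_mm = c(50, 100, 150, 200),
               y_mm = 120, chi = c(3, 3, 2, 1)))
  st <- match_marks(marks, refs)
  ds <- detection_summary(st)
  # hand enumeration: U marks 2 of 4 lesions (+1 FP), MC marks all 4
  expect_equal(ds$tp_rate$rate[ds$tp_rate$mode == "U"], 2 / 4)
  expect_equal(ds$tp_rate$rate[ds$tp_rate$mode == "MC"], 4 / 4)
  expect_equal(unname(ds$fp_counts), c(1, 0))
  # per-lesion dchi: A +1, B 0, C +2 (from imputed 0), D +1
  expect_equal(unname(ds$dchi$reader_1), c(1, 0, 2, 1))
})
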