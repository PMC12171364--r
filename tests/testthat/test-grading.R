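test_that("leaf death rate is the dead-over-total area percentage", {
  expect_equal(leaf_death_rate(0, 100), 0)
  expect_equal(leaf_death_rate(17.4, 17.4), 100)
  # printed areas are rounded, so the ratio lands near the printed rate
  expect_equal(leaf_death_rate(1.13, 17.4), 100 * 1.13 / 17.4)
  expect_lt(abs(leaf_death_rate(1.13, 17.4) - 6.52), 0.1)
  expect_error(leaf_death_rate(1, 0), "positive")
  expect_error(leaf_death_rate(5, 4), "dead_area")
})

test_that("grade bins follow the standard: boundaries belong to the lower grade", {
  expect_equal(assign_grade(6.52), 1L)
  expect_equal(assign_grade(45.57), 5L)
  expect_equal(assign_grade(10.0), 1L)
  expect_equal(assign_grade(100), 9L)
  # every printed boundary takes the lower grade; just above moves up
  expect_equal(assign_grade(c(10, 25, 50, 80)), c(1L, 3L, 5L, 7L))
  expect_equal(assign_grade(c(10, 25, 50, 80) + 1e-9), c(3L, 5L, 7L, 9L))
  expect_error(assign_grade(-1), "0, 100")
  expect_error(assign_grade(100.5), "0, 100")
})

test_that("assign_grade is monotone non-decreasing in death rate", {
  x <- sort(c(0, 100, withr::with_seed(5, runif(200, 0, 100))))
  g <- assign_grade(x)
  expect_true(all(diff(g) >= 0))
})

test_that("grade table construction is validated", {
  expect_error(grade_table(upper = c(10, 25, 50, 80, 90)), "Inf")
  expect_error(grade_table(upper = c(25, 10, 50, 80, Inf)), "increasing")
  expect_error(grade_table(grade = c(1, 2, 3, 4, 5)), "1, 3, 5, 7, 9")
})

test_that("survival is one green pixel anywhere; green leaves need a strict majority", {
  dead <- data.frame(instance_id = 1:2, pixel_count = c(10L, 20L),
                     green_count = c(0L, 0L), dead_count = c(10L, 20L))
  expect_false(is_alive(dead))
  one_green <- dead
  one_green$green_count[1] <- 1L
  one_green$dead_count[1] <- 9L
  expect_true(is_alive(one_green))
  expect_false(is_alive(dead[0, ]))

  mixed <- data.frame(instance_id = 1:3, pixel_count = c(10L, 10L, 10L),
                      green_count = c(6L, 5L, 0L),
                      dead_count = c(4L, 5L, 10L))
  expect_equal(count_green_leaves(mixed), 1L)  # exactly 1/2 does not count
  expect_equal(count_green_leaves(dead), 0L)
})

test_that("survival rate and green leaves per plant follow the cohort formulas", {
  expect_equal(survival_rate(6, 8), 75)
  expect_equal(survival_rate(0, 8), 0)
  expect_equal(survival_rate(8, 8), 100)
  expect_error(survival_rate(9, 8), "n_survivors")
  expect_error(survival_rate(1, 0), "positive")
  expect_equal(green_leaves_per_plant(24, 8), 3)
  expect_equal(green_leaves_per_plant(0, 5), 0)
  expect_equal(green_leaves_per_plant(11, 4), 2.75)
  expect_error(green_leaves_per_plant(3, 0), "zero survivors")
})

test_that("phenotype_plant pools pixels over all leaves", {
  one <- data.frame(instance_id = 1L, pixel_count = 100L,
                    green_count = 90L, dead_count = 10L)
  ph <- phenotype_plant(one)
  expect_equal(ph$death_rate_pct, 10)
  expect_equal(ph$grade, 1L)
  expect_true(ph$alive)

  two <- data.frame(instance_id = 1:2, pixel_count = c(100L, 100L),
                    green_count = c(60L, 20L), dead_count = c(40L, 80L))
  ph2 <- phenotype_plant(two)
  expect_equal(ph2$death_rate_pct, 60)
  expect_equal(ph2$grade, 7L)
  expect_equal(ph2$green_leaf_count, 1L)

  all_dead <- data.frame(instance_id = 1L, pixel_count = 50L,
                         green_count = 0L, dead_count = 50L)
  ph3 <- phenotype_plant(all_dead)
  expect_equal(ph3$death_rate_pct, 100)
  expect_equal(ph3$grade, 9L)
  expect_false(ph3$alive)

  expect_error(phenotype_plant(one[0, ]), "no plant")
})

test_that("variety summary pools pixels across replicates", {
  mk <- function(green, dead) phenotype_plant(data.frame(
    instance_id = 1L, pixel_count = green + dead,
    green_count = green, dead_count = dead))
  same <- replicate(8, mk(95L, 5L), simplify = FALSE)
  s <- summarize_variety("v1", same)
  expect_equal(s$pooled_death_rate_pct, 5)
  expect_equal(s$variety_grade, 1L)
  expect_equal(s$survival_rate_pct, 100)

  cohort <- c(replicate(6, mk(80L, 20L), simplify = FALSE),
              replicate(2, mk(0L, 100L), simplify = FALSE))
  s2 <- summarize_variety("v2", cohort)
  expect_equal(s2$n_survivors, 6L)
  expect_equal(s2$survival_rate_pct, 75)
  rates <- vapply(cohort, `[[`, numeric(1), "death_rate_pct")
  expect_gte(s2$pooled_death_rate_pct, min(rates))
  expect_lte(s2$pooled_death_rate_pct, max(rates))

  dead_cohort <- replicate(3, mk(0L, 10L), simplify = FALSE)
  s3 <- summarize_variety("v3", dead_cohort)
  expect_true(is.na(s3$green_leaves_per_plant))
  expect_equal(s3$survival_rate_pct, 0)
})

test_that("grading is invariant to uniform scaling of pixel counts", {
  base <- data.frame(instance_id = 1:2, pixel_count = c(120L, 80L),
                     green_count = c(100L, 10L), dead_count = c(20L, 70L))
  scaled <- base
  scaled[, 2:4] <- scaled[, 2:4] * 7L
  a <- phenotype_plant(base); b <- phenotype_plant(scaled)
  expect_equal(a$death_rate_pct, b$death_rate_pct)
  expect_equal(a$grade, b$grade)
  expect_equal(a$alive, b$alive)
  expect_equal(a$green_leaf_count, b$green_leaf_count)
})
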