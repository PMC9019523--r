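test_that("noiseless log-linear input is recovered to high precision", {
  yrs <- 1758:2013
  d <- data.frame(species = sprintf("s%d", seq_along(yrs)),
                  order = "O1", family = "F1", year = yrs,
                  mean_pd = 100 * exp(-0.01 * (yrs - 1758)))
  fit <- suppressWarnings(fit_decline(d, "year"))  # perfect-fit warning
  expect_equal(fit$slope, -0.01, tolerance = 1e-10)
  expect_equal(fit$percent_decline, 100 * (1 - exp(-0.01)),
               tolerance = 1e-10)
  expect_lt(fit$slope_se, 1e-12)
  ## constant contributions: zero slope and decline
  d2 <- d
  d2$mean_pd <- 5
  fit2 <- suppressWarnings(fit_decline(d2, "year"))
  expect_equal(fit2$slope, 0, tolerance = 1e-12)
  expect_equal(fit2$percent_decline, 0, tolerance = 1e-10)
})

test_that("percent decline is invariant to rescaling contributions", {
  set.seed(51)
  d <- simulate_contributions(sim_config(n_species = 300, seed = 51))
  f1 <- fit_decline(d, "year")
  d$mean_pd <- d$mean_pd * 37.5
  f2 <- fit_decline(d, "year")
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_equal(f1$percent_decline, f2$percent_decline, tolerance = 1e-10)
})

test_that("from_x filters the fitting window and small fits error", {
  d <- simulate_contributions(sim_config(n_species = 200, seed = 52))
  f <- fit_decline(d, "year", from_x = 1780)
  expect_equal(f$n_points, sum(d$year >= 1780 & d$mean_pd > 0))
  expect_error(fit_decline(d[1:2, ], "year"), "at least 3")
  fc <- fit_decline(d, "count")
  expect_equal(fc$x_variable, "count")
  expect_lt(fc$slope, 0)
})

test_that("per-order curves are additive and normalize to one", {
  tr <- worked_tree()
  cc <- mean_contributions(tr, worked_table(), n_perm = 5, seed = 1)
  oc <- per_order_curves(cc)
  ## one-species order: a 0 -> 1 step at its year
  o2 <- oc[oc$order == "O2", ]
  expect_equal(o2$pd_frac, 1)
  expect_equal(o2$year, 1850)
  ## final fraction of every order is one
  fin <- tapply(oc$pd_frac, oc$order, function(x) x[length(x)])
  expect_true(all(fin == 1))
  ## additivity: unnormalized order curves sum to the overall curve
  cy <- accumulation_curve(cc, "year")
  total_at <- function(y) sum(vapply(split(oc, oc$order), function(d) {
    i <- which(d$year <= y)
    if (length(i)) d$pd_cum[max(i)] else 0
  }, numeric(1)))
  for (k in seq_len(nrow(cy)))
    expect_equal(total_at(cy$x[k]), cy$pd[k], tolerance = 1e-12)
  ## single-order data: the order curve equals the overall curve
  tab1 <- worked_table()
  tab1$order <- "O1"
  cc1 <- mean_contributions(tr, tab1, n_perm = 5, seed = 1)
  oc1 <- per_order_curves(cc1)
  cy1 <- accumulation_curve(cc1, "year")
  expect_equal(oc1$pd_cum, cy1$pd)
})

test_that("decade matrices row-normalize and end at global shares", {
  set.seed(53)
  phy <- random_bd_tree(50)
  tab <- data.frame(species = phy$tip.label,
                    order = sample(c("Oa", "Ob", "Oc"), 50, replace = TRUE),
                    family = "F1",
                    year = sample(1758:2013, 50, replace = TRUE))
  cc <- mean_contributions(phy, tab, n_perm = 10, seed = 54)
  df <- decade_fractions(cc)
  expect_true(all(abs(rowSums(df$new_fraction) - 1) < 1e-12))
  last <- df$cumulative_fraction[nrow(df$cumulative_fraction), ]
  shares <- tapply(cc$mean_pd, cc$order, sum) / sum(cc$mean_pd)
  expect_equal(as.numeric(last[names(shares)]), as.numeric(shares),
               tolerance = 1e-12)
  ## worked example: the 1800s decade is all order O1
  cc3 <- mean_contributions(worked_tree(), worked_table(),
                            n_perm = 5, seed = 1)
  df3 <- decade_fractions(cc3)
  expect_equal(unname(df3$new_fraction["1800", "O1"]), 1)
})

test_that("most distinctive species per decade follow the tie rules", {
  cc <- mean_contributions(worked_tree(), worked_table(),
                           n_perm = 5, seed = 1)
  dd <- distinctive_per_decade(cc)
  expect_equal(dd$species[dd$decade == 1850], "C")
  expect_equal(dd$contribution[dd$decade == 1850], 3)
  ## singleton decade returns its only species
  expect_equal(dd$species[dd$decade == 1800], "B")
  ## equal means: earlier year wins, then name
  d <- data.frame(species = c("b", "a"), order = "O", family = "F",
                  year = c(1901L, 1905L), mean_pd = c(2, 2))
  expect_equal(distinctive_per_decade(d)$species, "b")
  d2 <- data.frame(species = c("b", "a"), order = "O", family = "F",
                   year = c(1901L, 1901L), mean_pd = c(2, 2))
  expect_equal(distinctive_per_decade(d2)$species, "a")
})

test_that("recent increment averages the trailing window", {
  d <- data.frame(species = letters[1:6], order = "O", family = "F",
                  year = c(1800L, 1900L, 1990L, 2000L, 2010L, 2013L),
                  mean_pd = c(50, 20, 4, 3, 2, 3))
  expect_equal(recent_increment(d, 50), mean(c(4, 3, 2, 3)))
  expect_equal(recent_increment(d, 1000), mean(d$mean_pd))
  expect_error(recent_increment(d[0, ], 50))
  ## declining series: recent increment below the overall mean
  dd <- simulate_contributions(sim_config(n_species = 400, seed = 55))
  expect_lt(recent_increment(dd, 50), mean(dd$mean_pd))
})
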