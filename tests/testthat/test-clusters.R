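test_that("pairwise distance matrix is symmetric with closed-form extremes", {
  one <- data.frame(zoo_id = "a", latitude = 10, longitude = 10)
  expect_equal(pairwise_distance_matrix(one),
               matrix(0, 1, 1, dimnames = list("a", "a")))

  anti <- data.frame(zoo_id = c("a", "b"), latitude = c(0, 0),
                     longitude = c(0, -180))
  d <- pairwise_distance_matrix(anti)
  expect_equal(d["a", "b"], 6371 * pi, tolerance = 1e-9)

  set.seed(5)
  zoos <- data.frame(zoo_id = letters[1:6],
                     latitude = stats::runif(6, -80, 80),
                     longitude = stats::runif(6, -180, 179))
  dm <- pairwise_distance_matrix(zoos)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    expect_lte(dm[i, k], dm[i, j] + dm[j, k] + 1e-8)
  }
})

test_that("metapopulation size sums member-zoo holdings", {
  ds <- make_cluster_toy()
  expect_equal(metapopulation_size("tx", "A", ds$holdings), 20)
  expect_equal(metapopulation_size("tx", c("A", "B", "D"), ds$holdings), 40)
  expect_equal(metapopulation_size("tx", c("A", "B", "C", "D"), ds$holdings), 60)
  expect_equal(metapopulation_size("far", c("A", "B"), ds$holdings), 0)
})

test_that("eligibility uses the at-least-m rule on network totals", {
  ds <- make_toy_dataset()
  # threatened Mammalia: p1 (total 8), p3 (total 120)
  expect_equal(eligible_species(ds, "Mammalia", 50), "p3")
  expect_equal(eligible_species(ds, "Mammalia", 120), "p3")   # boundary: >= m
  expect_equal(eligible_species(ds, "Mammalia", 121), character(0))
  expect_equal(eligible_species(ds, "Mammalia", 120, strict = TRUE),
               character(0))                                  # strict: > m
  expect_equal(eligible_species(ds, "Aves", 10), "a2")
})

test_that("exhaustive engine reproduces the hand-enumerated 4-zoo toy", {
  ds <- make_cluster_toy()
  dmat <- pairwise_distance_matrix(ds$zoos)
  # focal A, B or C: cluster {A,B,C}, N = 60 >= 50; focal D: N = 0
  ex <- exhaustive_cluster_probability("tx", 150, 50, dmat, ds$holdings)
  expect_equal(ex$p, 3 / 4)
  expect_equal(ex$mean_zoos, (3 + 3 + 3 + 1) / 4)
  expect_equal(ex$mean_zoos_with_species, (3 + 3 + 3 + 0) / 4)

  # single-zoo network with count >= m: certainty at radius 0
  solo <- data.frame(zoo_id = "only", latitude = 0, longitude = 0)
  h <- data.frame(zoo_id = "only", species_id = "tx", count = 80L)
  expect_equal(exhaustive_cluster_probability(
    "tx", 0, 50, pairwise_distance_matrix(solo), h)$p, 1)
})

test_that("Monte Carlo engine agrees with the exhaustive oracle on the toy", {
  ds <- make_cluster_toy()
  dmat <- pairwise_distance_matrix(ds$zoos)
  S <- 2000
  mc <- mc_cluster_probability("tx", 150, 50, dmat, ds$holdings,
                               iterations = S, seed = 21)
  p_true <- 0.75
  se <- sqrt(p_true * (1 - p_true) / S)
  expect_lt(abs(mc$p - p_true), 3 * se + 1 / S)
  # reproducible
  mc2 <- mc_cluster_probability("tx", 150, 50, dmat, ds$holdings,
                                iterations = S, seed = 21)
  expect_identical(mc, mc2)
})

test_that("species curve steps from 3/4 to 1 when the far zoo joins", {
  ds <- make_cluster_toy()
  cv <- species_cluster_curve(ds, "tx", 50, grid = radius_grid(10000, 100))
  expect_s3_class(cv, "cluster_curve")
  expect_equal(cv$curve$p[cv$curve$radius_km == 150 - 50], 3 / 4) # 100 km
  expect_equal(cv$curve$p[cv$curve$radius_km == 10000], 1)
  # non-decreasing (nested clusters)
  expect_true(all(diff(cv$curve$p) >= 0))

  # ineligible species: directed to eligible_species
  expect_error(species_cluster_curve(ds, "tx", 100), "eligible_species")
  expect_error(species_cluster_curve(ds, "nosuch", 50), "never reaches")

  # species with count >= m everywhere: certainty at every radius
  zoos <- ds$zoos
  h <- data.frame(zoo_id = zoos$zoo_id, species_id = "ubiq", count = 60L)
  sp <- data.frame(species_id = "ubiq", class_name = "Reptilia",
                   order_name = "Testudines", category = "CR")
  ds2 <- validate_dataset(zoos, sp, h, ds$checklist)
  cv2 <- species_cluster_curve(ds2, "ubiq", 50, grid = c(100, 5000))
  expect_equal(cv2$curve$p, c(1, 1))
})

test_that("ratio curve averages p/d and the optimum obeys the tie rule", {
  ds <- make_cluster_toy()
  grid <- c(100, 200, 400)
  curves <- class_cluster_curves(ds, "Reptilia", 50, grid = grid)
  expect_named(curves, c("far", "tx"))  # sorted species ids

  rc <- class_ratio_curve(curves, "Reptilia")
  P <- vapply(curves, function(cv) cv$curve$p, numeric(3))
  expect_equal(rc$curve$ratio, rowMeans(P) / grid)
  expect_equal(rc$n_species, 2)

  # single species with p = 1 everywhere: R = 1/d, strictly decreasing,
  # so the optimum is the first grid point
  zoos <- ds$zoos
  h <- data.frame(zoo_id = zoos$zoo_id, species_id = "ubiq", count = 60L)
  sp <- data.frame(species_id = "ubiq", class_name = "Reptilia",
                   order_name = "Testudines", category = "CR")
  ds2 <- validate_dataset(zoos, sp, h, ds$checklist)
  cvs <- class_cluster_curves(ds2, "Reptilia", 50, grid = grid)
  rc2 <- class_ratio_curve(cvs, "Reptilia")
  expect_equal(rc2$curve$ratio, 1 / grid)
  opt <- optimal_cluster(rc2, cvs)
  expect_equal(opt$radial_distance_km, 100)
  expect_equal(opt$probability, 1)

  # exact tie between two radii -> smallest wins
  fake <- structure(list(class_name = "X", m = 50, n_species = 1,
                         curve = data.frame(radius_km = c(100, 200, 400),
                                            ratio = c(0.1, 0.3, 0.3))),
                    class = "ratio_curve")
  fake_cv <- list(structure(list(species_id = "s", m = 50, engine = "exhaustive",
                                 iterations = NA_integer_, seed = NULL,
                                 curve = data.frame(radius_km = c(100, 200, 400),
                                                    p = c(0.1, 0.6, 0.9),
                                                    mean_zoos = c(1, 2, 3),
                                                    mean_zoos_with_species = c(1, 1, 2))),
                            class = "cluster_curve"))
  expect_equal(optimal_cluster(fake, fake_cv)$radial_distance_km, 200)

  expect_error(class_ratio_curve(list(), "Aves"), "no eligible species")
})

test_that("hand-computed two-species ratio picks the constructed optimum", {
  # p1 = (0.2, 0.9, 0.95), p2 = (0.0, 0.9, 1.0) on grid (100, 300, 900):
  # R = (0.1/100, 0.9/300, 0.975/900) = (0.001, 0.003, 0.00108) -> r* = 300
  grid <- c(100, 300, 900)
  mk <- function(id, p) structure(
    list(species_id = id, m = 50, engine = "exhaustive",
         iterations = NA_integer_, seed = NULL,
         curve = data.frame(radius_km = grid, p = p,
                            mean_zoos = c(2, 5, 9),
                            mean_zoos_with_species = c(1, 2, 4))),
    class = "cluster_curve")
  curves <- list(s1 = mk("s1", c(0.2, 0.9, 0.95)),
                 s2 = mk("s2", c(0.0, 0.9, 1.0)))
  rc <- class_ratio_curve(curves, "Mammalia")
  expect_equal(rc$curve$ratio, c(0.1 / 100, 0.9 / 300, 0.975 / 900))
  opt <- optimal_cluster(rc, curves)
  expect_equal(opt$radial_distance_km, 300)
  expect_equal(opt$probability, 0.9)
  expect_equal(opt$avg_zoos_in_cluster, 5)
  expect_equal(opt$avg_zoos_with_species, 2)
})

test_that("monotonicity, saturation and threshold ordering on synthetic data", {
  gen <- generate_dataset(make_null_scenario(13L))
  ds <- gen$dataset
  dmat <- pairwise_distance_matrix(ds$zoos)
  diam <- max(dmat)
  grid <- c(seq(500, 10000, by = 1500), ceiling(diam) + 1)
  for (cl in unique(ds$species$class_name)) {
    for (m in c(50, 100, 250)) {
      curves <- class_cluster_curves(ds, cl, m, grid = grid)
      for (cv in curves) {
        expect_true(all(diff(cv$curve$p) >= -1e-12))
        expect_equal(cv$curve$p[length(grid)], 1)  # saturation past diameter
      }
    }
    n_elig <- vapply(c(50, 100, 250),
                     function(m) length(eligible_species(ds, cl, m)), numeric(1))
    expect_true(all(diff(n_elig) <= 0))  # eligible counts non-increasing in m
  }
})

test_that("cluster_report produces the optimal-cluster table schema", {
  ds <- make_cluster_toy()
  tab <- suppressMessages(cluster_report(ds, thresholds = c(50, 60),
                                         grid = c(100, 5000, 6000)))
  expect_equal(names(tab),
               c("class", "threshold", "species_in_cluster",
                 "radial_distance_km", "probability", "avg_zoos_in_cluster",
                 "avg_zoos_with_species"))
  expect_equal(tab$class, c("Reptilia", "Reptilia"))
  expect_equal(tab$threshold, c(50, 60))
  # at m = 60 only "far" (60) and "tx" (60) both qualify at >= rule
  expect_equal(tab$species_in_cluster, c(2, 2))

  long <- curves_to_df(class_cluster_curves(ds, "Reptilia", 50,
                                            grid = c(100, 5000)))
  expect_equal(nrow(long), 4)
  expect_equal(names(long), c("species", "radius_km", "p", "mean_zoos",
                              "mean_zoos_with_species"))
})
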