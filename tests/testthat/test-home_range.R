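# Kernel UDs, ad-hoc bandwidth, isopleths, MCPs, availability sampling,
# zonal summaries and the asymptote check.

test_that("KDE mass normalises and the Gaussian closed form holds", {
  set.seed(18)
  sigma <- 120; h <- 40
  pts <- cbind(rnorm(5000, 0, sigma), rnorm(5000, 0, sigma))
  ud <- fit_kde(pts, h = h)
  expect_equal(sum(ud$grid$values), 1, tolerance = 1e-9)
  area <- isopleth(ud, 0.95)$area_m2
  analytic <- pi * (sigma^2 + h^2) * qchisq(0.95, 2)
  expect_lt(abs(area - analytic) / analytic, 0.10)
  expect_error(fit_kde(pts, h = -1), "h must be")
  expect_error(fit_kde(pts[1:3, ], h = 10), "at least 5")
})

test_that("halving the KDE cell size changes the isopleth area by < 2%", {
  set.seed(19)
  pts <- cbind(rnorm(800, 0, 100), rnorm(800, 0, 100))
  a1 <- isopleth(fit_kde(pts, 50, grid_resolution = 12.5))$area_m2
  a2 <- isopleth(fit_kde(pts, 50, grid_resolution = 6.25))$area_m2
  expect_lt(abs(a1 - a2) / a2, 0.02)
})

test_that("ad-hoc bandwidth shrinks until fragmentation and is scale-equivariant", {
  set.seed(20)
  pts <- cbind(rnorm(300, 0, 100), rnorm(300, 0, 100))
  h <- h_ad_hoc(pts)
  h_ref <- attr(h, "h_ref")
  expect_lt(as.numeric(h), h_ref)
  # oracle re-check: contiguous at the returned h, fragmented one step below
  contig <- function(p, hh) {
    m <- quollmove:::isopleth_mask(fit_kde(p, hh), 0.95)
    quollmove:::n_components(m) == 1 && !quollmove:::has_holes(m)
  }
  expect_true(contig(pts, as.numeric(h)))
  nxt <- as.numeric(h) - 0.05 * h_ref
  if (nxt > 0.03 * h_ref) expect_false(contig(pts, nxt))

  # two clusters far apart fragment immediately -> h_ref returned
  far <- rbind(cbind(rnorm(100, 0, 1), rnorm(100, 0, 1)),
               cbind(rnorm(100, 300, 1), rnorm(100, 300, 1)))
  hf <- h_ad_hoc(far)
  expect_equal(as.numeric(hf), attr(hf, "h_ref"))

  # scale equivariance within one shrink step
  h10 <- h_ad_hoc(pts * 10)
  expect_lt(abs(as.numeric(h10) / 10 - as.numeric(h)),
            0.05 * h_ref + 1e-9)
})

test_that("isopleth takes the smallest prefix of cells and nests by level", {
  vals <- matrix(1 / 100, 10, 10)
  ud <- structure(list(grid = raster_grid(vals, 0, 100, 10), h = 1,
                       n_points = 100, cell_area = 100),
                  class = "quoll_ud")
  r <- isopleth(ud, 0.95)
  expect_equal(sum(r$mask), 95)
  expect_equal(r$area_m2, 9500)

  set.seed(22)
  m <- matrix(rexp(400), 20, 20); m <- m / sum(m)
  ud2 <- structure(list(grid = raster_grid(m, 0, 20, 1), h = 1,
                        n_points = 10, cell_area = 1),
                   class = "quoll_ud")
  expect_lte(isopleth(ud2, 0.5)$area_m2, isopleth(ud2, 0.95)$area_m2)
  # brute-force greedy selection oracle
  v <- sort(as.vector(m), decreasing = TRUE)
  brute_k <- which(cumsum(v) >= 0.95)[1]
  expect_equal(sum(isopleth(ud2, 0.95)$mask), brute_k)
})

test_that("MCP area and hull match brute force", {
  sq <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(mcp(sq)$area_m2, 1.0)
  expect_warning(col <- mcp(cbind(1:5, 1:5)), "degenerate")
  expect_equal(col$area_m2, 0)

  set.seed(23)
  pts <- cbind(runif(200), runif(200))
  hull <- mcp(pts)$vertices
  # gift wrapping oracle
  wrap <- function(p) {
    start <- which.min(p[, 2] * 1e6 + p[, 1])
    idx <- start; cur <- start
    repeat {
      cand <- setdiff(seq_len(nrow(p)), cur)
      nxt <- cand[1]
      for (k in cand[-1]) {
        cr <- (p[nxt, 1] - p[cur, 1]) * (p[k, 2] - p[cur, 2]) -
          (p[nxt, 2] - p[cur, 2]) * (p[k, 1] - p[cur, 1])
        if (cr < 0 || (cr == 0 &&
              sum((p[k, ] - p[cur, ])^2) > sum((p[nxt, ] - p[cur, ])^2)))
          nxt <- k
      }
      if (nxt == start) break
      idx <- c(idx, nxt); cur <- nxt
    }
    p[idx, , drop = FALSE]
  }
  oracle <- wrap(pts)
  expect_setequal(apply(round(hull, 10), 1, paste, collapse = ","),
                  apply(round(oracle, 10), 1, paste, collapse = ","))
})

test_that("equal-area radius reproduces the study's buffer radius", {
  r <- sqrt(8576.21 * 1e4 / pi)
  expect_equal(r, 5224.65, tolerance = 1e-4)
  expect_lt(abs(r - 5220) / 5220, 0.001)
})

test_that("available ranges are uniform over the availability region with exact areas", {
  sq <- mcp(cbind(c(0, 0, 1000, 1000), c(0, 1000, 0, 1000)))
  region <- availability_region(sq, r_max = 300, r_focal = 300) # zero buffer
  target <- pi * 150^2
  rngs <- sample_available_ranges(region, target, n = 5, seed = 24,
                                  individual_id = "A")
  expect_length(rngs, 5)
  for (r in rngs) {
    expect_equal(r$area_m2, target)
    expect_equal(r$radius, sqrt(target / pi))
    expect_equal(r$range_type, "available")
  }
  # 9 individuals x 5 -> 45 available ranges
  expect_equal(9 * length(rngs), 45)

  set.seed(25)
  many <- sample_available_ranges(region, target, n = 10000)
  cx <- vapply(many, function(r) r$centroid[["x"]], numeric(1))
  cy <- vapply(many, function(r) r$centroid[["y"]], numeric(1))
  counts <- table(cut(cx, seq(0, 1000, 250)), cut(cy, seq(0, 1000, 250)))
  p <- suppressWarnings(chisq.test(as.vector(counts)))$p.value
  expect_gt(p, 0.001)
  # buffered region contains the MCP and warns when undersized
  reg2 <- availability_region(sq, r_max = 600, r_focal = 100)
  expect_gt(reg2$area_m2, sq$area_m2)
  expect_warning(sample_available_ranges(reg2, 1e12, n = 1, seed = 1),
                 "smaller")
})

test_that("zonal summaries match brute-force per-cell scans", {
  land <- mono_landscape("rocky", n = 40)
  circ <- structure(list(individual_id = "A", range_type = "observed",
                         level = 0.95, radius = 120,
                         centroid = c(x = 200, y = 200),
                         area_m2 = pi * 120^2, area_ha = pi * 120^2 / 1e4,
                         equal_area_radius = 120),
                    class = "movement_range")
  s <- summarize_range(circ, land)
  expect_equal(s$prop_rocky, 1.0)
  expect_equal(s$mean_dist_rocky, 0)

  # 50/50 vertical split landscape
  split_hab <- raster_grid(cbind(matrix(0, 40, 20), matrix(2, 40, 20)),
                           0, 400, 10, name = "habitat")
  land2 <- list(habitat = split_hab,
                tri = raster_grid(matrix(1, 40, 40), 0, 400, 10, name = "tri"),
                dist_disturbance = raster_grid(matrix(5, 40, 40), 0, 400, 10),
                dist_rocky = raster_grid(
                  distance_transform(cbind(matrix(FALSE, 40, 20),
                                           matrix(TRUE, 40, 20)), 10),
                  0, 400, 10))
  class(land2) <- "quoll_landscape"
  circ2 <- circ; circ2$centroid <- c(x = 200, y = 200)
  s2 <- summarize_range(circ2, land2)
  expect_lt(abs(s2$prop_rocky - 0.5), 0.05)
  expect_lt(abs(s2$prop_spinifex - 0.5), 0.05)

  # brute-force oracle over all cells
  cc <- raster_centres(land2$habitat)
  inside <- (as.vector(cc$xm) - 200)^2 + (as.vector(cc$ym) - 200)^2 <= 120^2
  expect_equal(s2$prop_rocky, mean(land2$habitat$values[inside] == 2))
  expect_equal(s2$mean_dist_rocky, mean(land2$dist_rocky$values[inside]))
  expect_equal(s2$median_tri, 1)
})

test_that("asymptote check flags stationary sampling and short tracks", {
  set.seed(26)
  pts <- cbind(rnorm(600, 0, 80), rnorm(600, 0, 80))
  chk <- asymptote_check(pts, interval = 20)
  expect_true(all(is.finite(chk$areas_ha)) && all(chk$areas_ha > 0))
  expect_true(chk$reached)
  short <- asymptote_check(pts[1:25, ], interval = 10)
  expect_false(short$reached)
})
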