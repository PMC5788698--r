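test_that("synapse area is the chord sum times section thickness", {
  s <- synapse_profile_series(
    data.frame(section = 1:3, az_id = "az1", chord_nm = c(300, 400, 300),
               perforated = FALSE), section_thickness = 60)
  sa <- synapse_area(s)
  expect_equal(sa$total_um2, 0.06)
  expect_equal(sa$per_az$area_um2, 0.06)
  empty <- synapse_profile_series(
    data.frame(section = integer(0), az_id = character(0),
               chord_nm = numeric(0), perforated = logical(0)), 60)
  expect_warning(sa0 <- synapse_area(empty),
                 class = "cristamorph_empty_series_warning")
  expect_equal(sa0$total_um2, 0)
})

test_that("synapse area and Cavalieri volume are linear in thickness and
          order-invariant", {
  chords <- c(120, 310, 260, 90)
  mk <- function(t, perm = seq_along(chords)) {
    synapse_area(synapse_profile_series(
      data.frame(section = seq_along(chords), az_id = "a",
                 chord_nm = chords[perm], perforated = FALSE), t))$total_um2
  }
  expect_equal(mk(120), 2 * mk(60))
  expect_equal(mk(60, c(3, 1, 4, 2)), mk(60))
  areas <- c(1e5, 2.4e5, 1.7e5)
  expect_equal(cavalieri_volume(areas, 120), 2 * cavalieri_volume(areas, 60))
  expect_equal(cavalieri_volume(rev(areas), 60), cavalieri_volume(areas, 60))
})

test_that("Cavalieri volume is exact for a cylinder and converges for a
          sphere", {
  expect_equal(cavalieri_volume(rep(5e4, 7), 60), 7 * 5e4 * 60)
  b <- generate_serial_bouton(list(), mito_shape = list(kind = "sphere",
                                                        r_nm = 300),
                              section_thickness = 60)
  v <- cavalieri_volume(b$mito_areas_nm2, 60)
  expect_lt(abs(v - 4 / 3 * pi * 300^3) / (4 / 3 * pi * 300^3), 0.05)
  expect_warning(cavalieri_volume(numeric(0), 60),
                 class = "cristamorph_empty_series_warning")
})

test_that("serial slicing of a disc converges to the disc area", {
  truth <- pi * 150^2 / 1e6
  err <- sapply(c(60, 30, 15, 7.5), function(t) {
    b <- generate_serial_bouton(list(list(radius_nm = 150)),
                                section_thickness = t)
    abs(synapse_area(b$synapse)$total_um2 - truth) / truth
  })
  expect_lt(err[4], 0.01)
  expect_true(all(diff(err) < 0))
})

test_that("empty active-zone list yields no chords and zero area", {
  b <- generate_serial_bouton(list(), section_thickness = 60)
  expect_identical(nrow(b$synapse$profiles), 0L)
  expect_warning(expect_equal(synapse_area(b$synapse)$total_um2, 0))
  expect_equal(b$true_az_area_um2, 0)
})

test_that("shapes thinner than one section warn and give one section", {
  expect_warning(
    b <- generate_serial_bouton(list(list(radius_nm = 20)),
                                section_thickness = 60),
    class = "cristamorph_thin_shape_warning")
  expect_lte(nrow(b$synapse$profiles), 1L)
})

test_that("bouton classification implements the LP/HP rule with strict
          inequalities", {
  expect_identical(classify_bouton(1, FALSE, 0.05), "LP")
  expect_identical(classify_bouton(2, FALSE, 0.15), "HP")
  expect_identical(classify_bouton(1, TRUE, 0.15), "HP")
  # boundary cases stay unassigned: the rule is strict on both sides
  expect_identical(classify_bouton(1, FALSE, 0.09), "unclassified")
  expect_identical(classify_bouton(2, FALSE, 0.09), "unclassified")
  # mixed geometry that satisfies neither branch
  expect_identical(classify_bouton(1, FALSE, 0.3), "unclassified")
  expect_identical(classify_bouton(3, TRUE, 0.01), "unclassified")
  expect_error(classify_bouton(1, NA, 0.05),
               class = "cristamorph_validation_error")
})

test_that("every valid record lands in exactly one class", {
  set.seed(11)
  for (i in 1:200) {
    cls <- classify_bouton(sample(1:3, 1), runif(1) < 0.3,
                           runif(1, 0, 0.3))
    expect_true(cls %in% c("LP", "HP", "unclassified"))
  }
})

test_that("membrane association uses an inclusive 40-nm cutoff", {
  expect_identical(gold_is_membrane_associated(c(39, 40, 41)),
                   c(TRUE, TRUE, FALSE))
  expect_error(gold_is_membrane_associated(-1),
               class = "cristamorph_argument_error")
})

test_that("point-to-polyline distance is the segment-wise minimum", {
  poly <- rbind(c(0, 0), c(100, 0), c(100, 100))
  pts <- rbind(c(50, 30), c(150, 0), c(110, 50), c(0, -40))
  expect_equal(particle_membrane_distance(pts, poly),
               c(30, 50, 10, 40))
})

test_that("gold linear density matches the published control counts", {
  # straight membrane of known length with particles placed by hand
  poly <- rbind(c(0, 0), c(2000, 0))
  pts <- cbind(seq(100, 1900, length.out = 10), rep(10, 10))
  gd <- gold_linear_density(pts, poly)
  expect_equal(gd$density_per_um, 5.0)
  # knockout-like field: no particles over 74.8 um of membrane
  poly_ko <- rbind(c(0, 0), c(74.8e3, 0))
  gd0 <- gold_linear_density(matrix(numeric(0), 0, 2), poly_ko)
  expect_identical(gd0$density_per_um, 0)
  expect_equal(gd0$membrane_length_um, 74.8)
  # 188 associated particles over 38.6 um give the wild-type 4.87/um
  poly_wt <- rbind(c(0, 0), c(38.6e3, 0))
  pts_wt <- cbind(runif(188, 0, 38.6e3), runif(188, -35, 35))
  expect_equal(gold_linear_density(pts_wt, poly_wt)$density_per_um,
               188 / 38.6, tolerance = 1e-12)
  expect_equal(188 / 38.6, 4.87, tolerance = 0.001)
})

test_that("synthetic gold fields honor their generative parameters", {
  poly <- rbind(c(0, 2500), c(38600 / 4, 2500)) # 9.65 um inside field
  # distance_sigma = 0: all specific particles on the membrane
  f0 <- generate_gold_field(gold_field_spec(
    poly, specific_linear_density = 4.87, distance_sigma_nm = 0,
    field_size_nm = c(10000, 5000), seed = 3))
  d <- particle_membrane_distance(as.matrix(f0[, c("x_nm", "y_nm")]), poly)
  expect_lt(max(d), 1e-9)
  # zero density: background only
  fb <- generate_gold_field(gold_field_spec(
    poly, specific_linear_density = 0, background_areal_density = 2,
    field_size_nm = c(10000, 5000), seed = 4))
  expect_true(all(fb$truth_label == "background"))
  # Poisson mean: expected count = density x length
  counts <- vapply(1:40, function(s) {
    f <- generate_gold_field(gold_field_spec(
      poly, specific_linear_density = 4.87, seed = s,
      field_size_nm = c(10000, 5000)))
    sum(f$truth_label == "specific")
  }, numeric(1))
  expect_equal(mean(counts), 4.87 * 9.65, tolerance = 0.1)
})

test_that("estimated linear density approaches truth plus the predicted
          background term", {
  len_nm <- 30000
  poly <- rbind(c(5000, 15000), c(5000 + len_nm, 15000))
  bg <- 20 # particles/um^2
  cutoff <- 40
  dens <- vapply(1:30, function(s) {
    f <- generate_gold_field(gold_field_spec(
      poly, specific_linear_density = 4.87, distance_sigma_nm = 10,
      background_areal_density = bg, field_size_nm = c(40000, 30000),
      seed = 100 + s))
    gold_linear_density(as.matrix(f[, c("x_nm", "y_nm")]), poly,
                        cutoff_nm = cutoff)$density_per_um
  }, numeric(1))
  # background adds ~ areal density x band width (2 x cutoff);
  # sigma = 10 nm keeps essentially all specific particles in the band
  expected <- 4.87 + bg * 2 * cutoff / 1000
  expect_equal(mean(dens), expected, tolerance = 0.05)
})

test_that("bouton records assemble geometry, volume and class", {
  b <- generate_serial_bouton(list(list(radius_nm = 120)),
                              mito_shape = list(kind = "sphere", r_nm = 250),
                              section_thickness = 60)
  rec <- bouton_record(b$synapse, b$mito_areas_nm2, id = "b1")
  expect_identical(rec$class, "LP") # single nonperforated AZ below 0.09
  expect_equal(rec$mito_volume_nm3,
               cavalieri_volume(b$mito_areas_nm2, 60))
})
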