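# Phantom generator: determinism, geometry, intensity ordering, lesions.

test_that("phantom generation is deterministic and counter-stable", {
  spec <- phantom_spec(resolution = 32, seed = 42)
  a <- generate_phantom(spec, 5)
  b <- generate_phantom(spec, 5)
  expect_identical(a, b)                      # same seed -> bit-identical
  c3 <- generate_phantom(spec, 3)
  expect_identical(a$images[[2]], c3$images[[2]])  # sample i independent of n
  # population varies across samples
  expect_gt(mean((a$images[[1]] - a$images[[2]])^2), 0)
})

test_that("degenerate spec yields a piecewise-constant annulus-plus-disk image", {
  spec <- phantom_spec(resolution = 32, ventricle_count = 0,
                       tissue_contrast = 0, noise_sd = 0, seed = 5)
  img <- generate_phantom(spec, 1)$images[[1]]
  expect_true(all(unique(as.vector(img)) %in% c(0, 0.35, 0.95)))
})

test_that("skull annulus is brighter than interior tissue and values are unit", {
  spec <- phantom_spec(resolution = 32, seed = 11)
  ds <- generate_phantom(spec, 6)
  for (img in ds$images) {
    expect_true(min(img) >= 0 && max(img) <= 1)
    brain <- attr(img, "brain_mask")
    skull <- img > 0.8 & !brain
    expect_gt(mean(img[skull]), mean(img[brain]))
  }
})

test_that("insert_anomaly is local, exact, and clamped", {
  spec <- phantom_spec(resolution = 32, seed = 2)
  img <- generate_phantom(spec, 1)$images[[1]]
  # radius 0: unchanged image, empty mask
  r0 <- insert_anomaly(img, anomaly_spec("bright_blob", c(16, 16), 0, 0.3))
  expect_identical(unclass(r0$image), unclass(img))
  expect_false(any(r0$mask))
  # disk footprint matches brute-force rasterization for several radii
  for (rad in c(1, 2.5, 4)) {
    les <- insert_anomaly(img, anomaly_spec("bright_blob", c(16, 16), rad, 0.3))
    expect_equal(sum(les$mask), oracle_disk_area(rad))
    # pixels outside the mask differ by exactly zero
    expect_identical(unclass(les$image)[!les$mask], unclass(img)[!les$mask])
    expect_true(all(les$image >= 0 & les$image <= 1))
  }
  # bright blob raises mean intensity inside the mask by ~delta
  les <- insert_anomaly(img, anomaly_spec("bright_blob", c(16, 16), 4, 0.25))
  expect_equal(mean(les$image[les$mask]) - mean(img[les$mask]), 0.25,
               tolerance = 1e-8)
})

test_that("lesions outside the brain or image are rejected", {
  spec <- phantom_spec(resolution = 32, seed = 2)
  img <- generate_phantom(spec, 1)$images[[1]]
  expect_error(insert_anomaly(img, anomaly_spec("bright_blob", c(6, 6), 2, 0.3)),
               "brain region")
  expect_error(insert_anomaly(img, anomaly_spec("bright_blob", c(1, 16), 3, 0.3)),
               "outside the image")
  expect_error(anomaly_spec("bright_blob", c(16, 16), 3, -0.2), "must be > 0")
})

test_that("lesioned datasets carry exact masks inside the brain", {
  spec <- phantom_spec(resolution = 32, seed = 9)
  ds <- phantom_with_lesions(spec, 5, "bright_blob")
  expect_length(ds$masks, 5)
  for (i in seq_along(ds$images)) {
    expect_true(any(ds$masks[[i]]))
    brain <- attr(ds$images[[i]], "brain_mask")
    expect_true(all(brain[ds$masks[[i]]]))
  }
  # textured masses perturb the footprint with texture but stay local
  dt <- phantom_with_lesions(spec, 2, "textured_mass")
  expect_true(all(vapply(dt$masks, any, logical(1))))
})
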