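# synthetic face generator, pair derivation, cohort simulation

test_that("generation is deterministic: same params give byte-identical STL", {
  p <- face_params(resolution = 60)
  f1 <- generate_face(p, min_region_vertices = 3)
  f2 <- generate_face(p, min_region_vertices = 3)
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  write_stl(f1$mesh, t1)
  write_stl(f2$mesh, t2)
  expect_identical(readBin(t1, "raw", file.size(t1)),
                   readBin(t2, "raw", file.size(t2)))
})

test_that("atlas hosts all 23 regions with at least 20 vertices at default resolution", {
  f <- generate_face(face_params())
  counts <- table(f$atlas)
  expect_setequal(names(counts), atlas_region_names())
  expect_length(atlas_region_names(), 23)
  expect_true(all(counts >= 20))
  # resolution floor and coverage error
  expect_error(face_params(resolution = 20), "at least 30")
  expect_error(generate_face(face_params(resolution = 40)), "too low")
})

test_that("the face is bilaterally symmetric: L/R region centroids mirror", {
  f <- generate_face(face_params(resolution = 60), min_region_vertices = 3)
  v <- f$mesh$vertices
  lr <- c("ala nasi", "nasal bridge", "sulcus nasolabialis",
          "oral/labial commissure", "orbital region")
  for (base in lr) {
    cl <- colMeans(v[!is.na(f$atlas) & f$atlas == paste(base, "L"), , drop = FALSE])
    cr <- colMeans(v[!is.na(f$atlas) & f$atlas == paste(base, "R"), , drop = FALSE])
    expect_lt(max(abs(cl - cr * c(-1, 1, 1))), 1e-6)
  }
})

test_that("null perturbation leaves only decimation error (< 0.3 mm per-region p95)", {
  f <- generate_face(face_params())
  pr <- derive_pair(f, perturbation_spec(noise_sd = 0, concavity_gain = 0),
                    seed = 1)
  fld <- absolute_deviation(pr$scan, pr$shell)
  s <- summarize_regions(fld, pr$scan_atlas)
  expect_true(all(s$assessable))
  expect_lt(max(s$p95_mm), 0.3)
})

test_that("ground-truth bookkeeping is exact and offsets are recovered within 0.2 mm", {
  f <- generate_face(face_params())
  spec <- perturbation_spec(offsets = c("orbital region L" = 4,
                                        "vermilion" = 5,
                                        "mental region" = 2),
                            noise_sd = 0, concavity_gain = 0)
  pr <- derive_pair(f, spec, seed = 2)
  expect_equal(pr$truth$region_dev[["orbital region L"]], 4.0)
  expect_equal(pr$truth$region_dev[["philtrum"]], 0)
  # measure scan against the pre-misalignment shell directly (no registration)
  fld <- absolute_deviation(pr$scan, pr$shell, max_valid = 20)
  for (r in c("orbital region L", "vermilion", "mental region")) {
    sel <- !is.na(pr$scan_atlas) & pr$scan_atlas == r & fld$valid
    expect_lt(abs(mean(fld$raw[sel]) - pr$truth$region_dev[[r]]), 0.2)
  }
  expect_error(derive_pair(f, perturbation_spec(offsets = c("vermilion" = 12))),
               "self-intersect")
})

test_that("forehead crop removes the top of the frontal region's height span", {
  f <- generate_face(face_params(resolution = 60), min_region_vertices = 3)
  fy <- f$mesh$vertices[!is.na(f$atlas) & f$atlas == "frontal region", 2]
  thr <- min(fy) + 0.7 * diff(range(fy))
  pr <- derive_pair(f, perturbation_spec(forehead_crop = 0.3), seed = 1)
  expect_lt(max(pr$shell$vertices[, 2]), thr + 1e-9)
  expect_lt(nrow(pr$shell$vertices), nrow(f$mesh$vertices))
})

test_that("concavity-dependent noise degrades concave regions more than the nasal tip", {
  f <- generate_face(face_params())
  pr <- derive_pair(f, perturbation_spec(noise_sd = 0.05, concavity_gain = 1),
                    seed = 3)
  fld <- absolute_deviation(pr$scan, pr$shell)
  mae <- function(rn) {
    sel <- !is.na(pr$scan_atlas) & pr$scan_atlas %in% rn & fld$valid
    mean(fld$raw[sel])
  }
  concave <- mae(c("orbital region L", "orbital region R", "sulcus mentolabialis"))
  apex <- mae("apex of nose")
  expect_gt(concave, apex)
})

test_that("simulate_cohort: composition, determinism, flag-rate calibration", {
  cases <- simulate_cohort(seed = 10)
  expect_length(cases, 60)
  expect_equal(sum(vapply(cases, `[[`, "", "sex") == "M"), 19)
  expect_equal(sum(vapply(cases, `[[`, "", "sex") == "F"), 41)
  cases2 <- simulate_cohort(seed = 10)
  expect_identical(lapply(cases, `[[`, "truth_dev"),
                   lapply(cases2, `[[`, "truth_dev"))
  # orbital defect probability 0.65 over 600 subjects: inside binomial 99% CI
  prof <- deviation_profile(data.frame(region = "orbital region L",
                                       p_men = 0.65, p_women = 0.65))
  big <- simulate_cohort(300, 300, prof, seed = 4)
  hits <- sum(vapply(big, function(cs) cs$truth_dev[["orbital region L"]] > 3, TRUE))
  ci <- qbinom(c(0.005, 0.995), 600, 0.65)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("case bundles round-trip through their text formats", {
  cases <- simulate_cohort(2, 2, seed = 5,
                           face_parameters = face_params(resolution = 60))
  pair <- build_case(cases[[1]], min_region_vertices = 3)
  dir <- withr::local_tempdir()
  write_case_bundle(pair, dir)
  expect_setequal(list.files(dir),
                  c("shell.stl", "scan.stl", "landmarks.txt", "atlas.csv",
                    "truth.csv", "misalignment.txt"))
  shell <- read_stl(file.path(dir, "shell.stl"))
  expect_equal(nrow(shell$faces), nrow(pair$shell$faces))
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(truth$true_deviation_mm,
               as.numeric(pair$truth$region_dev[truth$region]))
  tr <- read_transform(file.path(dir, "misalignment.txt"))
  expect_rt_equal(tr, pair$truth$transform, tol = 1e-12)
})
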