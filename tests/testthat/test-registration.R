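# Kabsch, trimmed ICP, dual-operator stability

test_that("kabsch: identity, known transform recovery, reflection guard", {
  withr::local_seed(5)
  src <- matrix(runif(30, -10, 10), ncol = 3)
  # identity
  t0 <- kabsch(src, src)
  expect_rt_equal(t0, rigid_transform())
  # 90 degrees about z + translation
  tr <- rt_from_angles(c(0, 0, 90), c(1, 2, 3))
  rec <- kabsch(src, rt_apply(tr, src))
  expect_lt(max(abs(rt_apply(rec, src) - rt_apply(tr, src))), 1e-9)
  # mirrored target: must still return a proper rotation
  mir <- src %*% diag(c(-1, 1, 1))
  best <- kabsch(src, mir)
  expect_equal(det(best$rotation), 1, tolerance = 1e-9)
  # degenerate input
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch(line, line), "collinear")
  expect_error(kabsch(src[1:2, ], src[1:2, ]), "at least 3")
})

make_test_pair <- function(spec, seed = 1, resolution = 60) {
  face <- generate_face(face_params(resolution = resolution),
                        min_region_vertices = 3)
  derive_pair(face, spec, seed = seed)
}

test_that("icp converges immediately for an already-aligned identical pair", {
  face <- generate_face(face_params(resolution = 60), min_region_vertices = 3)
  rep <- icp(face$mesh, face$mesh, scan_atlas = face$atlas)
  expect_lte(rep$iterations, 2)
  expect_lt(rep$rms[length(rep$rms)], 1e-6)
  expect_true(rep$converged)
})

test_that("icp recovers a known noise-free misalignment to < 0.05 mm", {
  spec <- perturbation_spec(noise_sd = 0, concavity_gain = 0,
                            misalign_angles = c(5, -5, 5),
                            misalign_trans = c(3, -3, 3))
  # resolution 100: the 0.05 mm bound is below the faceting bias of the
  # coarse 60-grid used elsewhere in this file
  pr <- make_test_pair(spec, resolution = 100)
  rep <- register_pair(pr)
  # mean surface displacement between recovered and true inverse alignment
  truth_inv <- rt_invert(pr$truth$transform)
  d <- rt_apply(rep$transform, pr$scan$vertices) -
    rt_apply(truth_inv, pr$scan$vertices)
  expect_lt(mean(row_norms_test(d)), 0.05)
  # trimmed objective is non-increasing
  expect_true(all(diff(rep$rms) <= 0))
})

test_that("icp recovers misalignment under 0.15 mm noise to < 0.3 mm (Monte Carlo)", {
  errs <- vapply(1:6, function(s) {
    spec <- perturbation_spec(noise_sd = 0.15, concavity_gain = 0,
                              misalign_angles = c(4, 3, -4),
                              misalign_trans = c(-4, 4, 3))
    pr <- make_test_pair(spec, seed = s)
    rep <- register_pair(pr)
    truth_inv <- rt_invert(pr$truth$transform)
    mean(row_norms_test(rt_apply(rep$transform, pr$scan$vertices) -
                          rt_apply(truth_inv, pr$scan$vertices)))
  }, 0)
  expect_lt(mean(errs), 0.3)
})

test_that("registration is equivariant under a common rigid pre-transform", {
  spec <- perturbation_spec(misalign_angles = c(3, 2, -3),
                            misalign_trans = c(2, -2, 2))
  pr <- make_test_pair(spec)
  res0 <- analyze_pair(pr, run_config(min_region_vertices = 3))
  tr <- rt_from_angles(c(30, -40, 55), c(100, -50, 25))
  pr2 <- pr
  pr2$shell <- rt_apply(tr, pr$shell)
  pr2$scan <- rt_apply(tr, pr$scan)
  pr2$shell_landmarks <- rt_apply(tr, pr$shell_landmarks)
  pr2$scan_landmarks <- rt_apply(tr, pr$scan_landmarks)
  rownames(pr2$shell_landmarks) <- rownames(pr$shell_landmarks)
  rownames(pr2$scan_landmarks) <- rownames(pr$scan_landmarks)
  res1 <- analyze_pair(pr2, run_config(min_region_vertices = 3))
  expect_lt(max(abs(res1$summary$p95_mm - res0$summary$p95_mm)), 1e-6)
})

test_that("icp input validation", {
  face <- generate_face(face_params(resolution = 60), min_region_vertices = 3)
  bad <- face$mesh
  bad$vertices[1, 1] <- NaN
  expect_error(icp(bad, face$mesh, scan_atlas = face$atlas), "non-finite")
  expect_error(icp(face$mesh, face$mesh,
                   mask = alignment_mask(c("apex of nose")),
                   scan_atlas = rep(NA_character_, nrow(face$mesh$vertices))),
               "mask resolves")
  expect_error(icp(face$mesh, face$mesh), "scan_atlas is required")
  expect_error(alignment_mask(character(0)), "nonempty")
  expect_error(alignment_mask("no such region"), "not in the atlas")
})

test_that("dual-operator check: stable face pair agrees, symmetric sphere does not", {
  spec <- perturbation_spec(misalign_angles = c(2, -2, 2),
                            misalign_trans = c(2, 2, -2))
  pr <- make_test_pair(spec)
  init <- kabsch(pr$scan_landmarks, pr$shell_landmarks)
  chk <- dual_operator_check(pr$scan, pr$shell, init = init,
                             scan_atlas = pr$scan_atlas, n_restarts = 3,
                             jitter = c(3, 2), seed = 2)
  expect_true(chk$agreement)
  expect_lt(chk$max_p95_disagreement_mm, 0.1)
  # rotationally symmetric pair: deviations agree but alignments do not
  # (jitter exceeds the tessellation's facet-locking basin)
  sph <- icosphere(2, radius = 50)
  chk2 <- dual_operator_check(sph, sph, mask = NULL, n_restarts = 3,
                              jitter = c(30, 5), seed = 2)
  expect_false(chk2$agreement)
  expect_true(chk2$degenerate)
})
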