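make_toy_model <- function(n_res = 6, chain = "A", seed = 1) {
  set.seed(seed)
  atoms <- purrr::map_dfr(seq_len(n_res), function(r) {
    tibble::tibble(chain = chain, resno = r, resid = "ALA",
                   elety = c("N", "CA", "C", "O", "CB"),
                   x = r * 3 + c(-0.5, 0, 0.5, 0.8, 0.1),
                   y = rnorm(5), z = rnorm(5))
  })
  structure_model(atoms)
}

test_that("PDB round-trip preserves chains, residues and coordinates", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  m <- dplyr::bind_rows(make_toy_model(chain = "A", seed = 1),
                        make_toy_model(chain = "B", seed = 2))
  m <- structure_model(m)
  write_pdb(m, tmp)
  back <- read_pdb(tmp)
  expect_equal(unique(back$chain), c("A", "B"))
  expect_equal(nrow(back), nrow(m))
  expect_equal(back$x, m$x, tolerance = 1e-3) # PDB fixed-width precision
  expect_equal(back$resno, m$resno)
})

test_that("malformed and empty PDB files are rejected with their line", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    test", "END"), tmp)
  expect_error(read_pdb(tmp), class = "gabrisk_bad_structure")
  writeLines(c("ATOM      1  CA  ALA A   1      bad coords here"), tmp)
  expect_error(read_pdb(tmp), "line 1", class = "gabrisk_bad_structure")
  writeLines(sprintf("ATOM  %5d  CA  ALA A   1A   %8.3f%8.3f%8.3f", 1, 1, 2, 3),
             tmp)
  expect_error(read_pdb(tmp), "insertion", class = "gabrisk_bad_structure")
})

test_that("superposition recovers identity and undoes rigid motions", {
  m <- make_toy_model(n_res = 8)
  s <- superpose(m, m)
  expect_equal(s$rms, 0, tolerance = 1e-12)
  expect_equal(s$rotation, diag(3), tolerance = 1e-10)
  shifted <- m
  shifted$x <- m$x + 5
  s2 <- superpose(m, shifted)
  expect_equal(s2$rms, 0, tolerance = 1e-10)
  expect_equal(s2$model$x, m$x, tolerance = 1e-10)
  # arbitrary rotation + translation
  th <- 0.7; R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(m[, c("x", "y", "z")]) %*% R
  rot <- m; rot$x <- xyz[, 1] + 2; rot$y <- xyz[, 2] - 1; rot$z <- xyz[, 3] + 4
  s3 <- superpose(m, rot)
  expect_equal(s3$rms, 0, tolerance = 1e-9)
  expect_error(superpose(m[1:2, ], m[1:2, ]), class = "gabrisk_bad_structure")
})

test_that("superposition RMS equals the quaternion oracle on noisy point sets", {
  set.seed(6)
  m <- make_toy_model(n_res = 10)
  noisy <- m
  noisy$x <- m$x + rnorm(nrow(m), sd = 0.4)
  noisy$y <- m$y + rnorm(nrow(m), sd = 0.4)
  noisy$z <- m$z + rnorm(nrow(m), sd = 0.4)
  s <- superpose(m, noisy, selection = "all")
  P <- as.matrix(noisy[, c("x", "y", "z")])
  Q <- as.matrix(m[, c("x", "y", "z")])
  expect_equal(s$rms, quaternion_rms(P, Q), tolerance = 1e-10)
})

test_that("per-element RMS matches the naive double-loop oracle", {
  ens <- generate_structure_fixture(n_subunits = 2, ensemble_size = 2,
                                    jitter_sd = 0.3, seed = 17)
  ref <- ens$reference
  member <- ens$members[[1]]
  emap <- attr(ref, "element_map")
  mine <- element_rms(ref, member)
  oracle <- naive_element_rms(ref, member, emap)
  joined <- dplyr::inner_join(mine, oracle, by = c("chain", "element"))
  expect_equal(nrow(joined), nrow(mine))
  expect_equal(joined$sidechain_rms.x, joined$sidechain_rms.y,
               tolerance = 1e-10)
  expect_equal(joined$secondary_structure_rms.x,
               joined$secondary_structure_rms.y, tolerance = 1e-10)
})

test_that("identical models give zero RMS and displaced side chains score exactly", {
  ens <- generate_structure_fixture(n_subunits = 3, ensemble_size = 1)
  ref <- ens$reference
  expect_true(all(element_rms(ref, ref)$sidechain_rms < 1e-14, na.rm = TRUE))
  # displace one element's side chains 1 A; backbone anchors superposition
  ens1 <- generate_structure_fixture(n_subunits = 3,
                                     perturbed_elements = "A:M2",
                                     displacement = 1, ensemble_size = 1)
  fitted <- superpose(ref, ens1$members[[1]])$model
  er <- element_rms(ref, fitted)
  expect_equal(er$sidechain_rms[er$chain == "A" & er$element == "M2"], 1,
               tolerance = 1e-10)
  expect_true(all(er$sidechain_rms[!(er$chain == "A" & er$element == "M2")] <
                    1e-10))
  expect_true(all(er$secondary_structure_rms < 1e-10))
})

test_that("glycine-only elements report absent side-chain RMS, not zero", {
  gly <- purrr::map_dfr(1:4, function(r) {
    tibble::tibble(chain = "A", resno = r, resid = "GLY",
                   elety = c("N", "CA", "C", "O"),
                   x = r * 3 + c(-0.5, 0, 0.5, 0.7), y = 0, z = c(0, 1, 0, 1))
  })
  emap <- tibble::tibble(chain = "A", resno = 1:4, element = "loop F")
  m <- structure_model(gly, element_map = emap)
  er <- element_rms(m, m)
  expect_true(is.na(er$sidechain_rms))
  expect_equal(er$secondary_structure_rms, 0)
})

test_that("RMS is invariant to a common rigid transform and scales with displacement", {
  ens <- generate_structure_fixture(n_subunits = 2,
                                    perturbed_elements = "B:Cys-loop",
                                    displacement = 0.8, ensemble_size = 1)
  ref <- ens$reference; mem <- ens$members[[1]]
  rotate <- function(m, th) {
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
    xyz <- as.matrix(m[, c("x", "y", "z")]) %*% R
    m$x <- xyz[, 1] + 3; m$y <- xyz[, 2] - 7; m$z <- xyz[, 3] + 1
    m
  }
  er0 <- element_rms(ref, superpose(ref, mem)$model)
  er1 <- element_rms(rotate(ref, 1.1),
                     superpose(rotate(ref, 1.1), rotate(mem, 1.1))$model)
  expect_equal(er0$sidechain_rms, er1$sidechain_rms, tolerance = 1e-9)
  # monotone scaling (jitter off)
  for (k in c(0.5, 2)) {
    ensk <- generate_structure_fixture(n_subunits = 2,
                                       perturbed_elements = "B:Cys-loop",
                                       displacement = 0.8 * k,
                                       ensemble_size = 1)
    erk <- element_rms(ref, superpose(ref, ensk$members[[1]])$model)
    i <- erk$chain == "B" & erk$element == "Cys-loop"
    expect_equal(erk$sidechain_rms[i], k * er0$sidechain_rms[er0$chain == "B" &
                                                               er0$element == "Cys-loop"],
                 tolerance = 1e-9)
  }
})

test_that("ensemble averaging uses only the lowest-energy members and is order-invariant", {
  # perturb only the high-energy half: selection must exclude them
  ens <- generate_structure_fixture(perturbed_elements = "A:loop C",
                                    displacement = 2, ensemble_size = 20,
                                    perturb_members = 11:20)
  rep1 <- ensemble_rms(ens, n_lowest = 10)
  expect_false(any(rep1$flagged))
  # permuting member order changes nothing
  perm <- ens
  idx <- c(7, 3, 20, 1, 14, 5, 18, 2, 9, 16, 4, 11, 6, 19, 8, 13, 10, 15, 12, 17)
  perm$members <- ens$members[idx]
  rep2 <- ensemble_rms(perm, n_lowest = 10)
  expect_equal(as.data.frame(rep1), as.data.frame(rep2))
  # fewer members than requested: use all, record a warning
  small <- generate_structure_fixture(perturbed_elements = "A:loop C",
                                      displacement = 1, ensemble_size = 4)
  expect_warning(rep3 <- ensemble_rms(small, n_lowest = 10))
  expect_equal(attr(rep3, "n_used"), 4)
  expect_true(rep3$flagged[rep3$chain == "A" & rep3$element == "loop C"])
})

test_that("local/global classification follows the chains of flagged elements", {
  local_ens <- generate_structure_fixture(
    perturbed_elements = c("B:loop C", "B:M2"), displacement = 1,
    mutated_site = list(chain = "B", resno = 15))
  rloc <- ensemble_rms(local_ens)
  expect_equal(classify_perturbation(rloc), "local")
  global_ens <- generate_structure_fixture(
    perturbed_elements = c("B:loop C", "C:Cys-loop"), displacement = 1,
    mutated_site = list(chain = "B", resno = 15))
  rglo <- ensemble_rms(global_ens)
  expect_equal(classify_perturbation(rglo), "global")
  none <- generate_structure_fixture(displacement = 0)
  expect_equal(classify_perturbation(ensemble_rms(none)), "none")
})
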