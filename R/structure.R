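#' Construct a structure model
#'
#' A `structure_model` is a tibble of atoms (`chain`, `resno`, `resid`,
#' `elety`, `x`, `y`, `z` in Angstrom) carrying an optional per-model energy
#' and an element map (a tibble `chain`, `resno`, `element` assigning scored
#' residues to named structural elements such as "loop C", "Cys-loop" or
#' "M2").
#'
#' @param atoms data frame with the columns above.
#' @param energy per-model score (arbitrary energy units).
#' @param element_map per-residue element assignment, or `NULL`.
#' @return A tibble of class `structure_model`.
#' @export
structure_model <- function(atoms, energy = NA_real_, element_map = NULL) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) {
    abort(paste0("atoms are missing column(s): ", paste(miss, collapse = ", ")),
          class = "gabrisk_bad_structure")
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atom coordinates must be finite", class = "gabrisk_bad_structure")
  }
  out <- as_tibble(atoms[need])
  class(out) <- c("structure_model", class(out))
  attr(out, "energy") <- energy
  attr(out, "element_map") <- if (!is.null(element_map)) as_tibble(element_map) else NULL
  out
}

#' Expand element ranges to a per-residue element map
#'
#' @param ranges data frame with `chain`, `element`, `start`, `end`
#'   (inclusive residue numbers).
#' @return A tibble `chain`, `resno`, `element`.
#' @export
element_map_from_ranges <- function(ranges) {
  stopifnot(all(c("chain", "element", "start", "end") %in% names(ranges)))
  purrr::pmap_dfr(ranges, function(chain, element, start, end, ...) {
    tibble(chain = chain, resno = seq(start, end), element = element)
  })
}

#' Read a PDB file into a structure model
#'
#' Parses ATOM records with bio3d after a light structural validation pass
#' (malformed ATOM records are reported with their line number; insertion
#' codes are rejected).
#'
#' @param path path to a PDB file.
#' @param element_map optional per-residue element map to attach.
#' @param energy optional per-model energy to attach.
#' @return A [structure_model()].
#' @export
read_pdb <- function(path, element_map = NULL, energy = NA_real_) {
  lines <- readLines(path, warn = FALSE)
  atom_idx <- grep("^ATOM  |^HETATM", lines)
  if (!length(atom_idx)) {
    abort(paste0("no ATOM records in ", path), class = "gabrisk_bad_structure")
  }
  for (i in atom_idx) {
    ln <- lines[[i]]
    if (nchar(ln) < 54) {
      abort(paste0("malformed ATOM record at line ", i, " of ", path),
            class = "gabrisk_bad_structure")
    }
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (any(is.na(coords))) {
      abort(paste0("unparseable coordinates at line ", i, " of ", path),
            class = "gabrisk_bad_structure")
    }
    if (substr(ln, 27, 27) != " ") {
      abort(paste0("insertion codes are not supported (line ", i, " of ",
                   path, ")"), class = "gabrisk_bad_structure")
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  structure_model(
    tibble(chain = at$chain, resno = at$resno, resid = at$resid,
           elety = at$elety, x = at$x, y = at$y, z = at$z),
    energy = energy, element_map = element_map
  )
}

#' Write a structure model to a PDB file
#'
#' @param model a [structure_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- as.numeric(t(as.matrix(model[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(model)),
                   resno = model$resno, resid = model$resid,
                   chain = model$chain, elety = model$elety,
                   eleno = seq_len(nrow(model)))
  invisible(path)
}

match_atoms <- function(reference, mobile) {
  key <- c("chain", "resno", "elety")
  ref <- dplyr::mutate(reference, .ref_row = dplyr::row_number())
  mob <- dplyr::mutate(mobile, .mob_row = dplyr::row_number())
  m <- dplyr::inner_join(ref[, c(key, ".ref_row")], mob[, c(key, ".mob_row")],
                         by = key)
  m
}

#' Least-squares rigid-body superposition
#'
#' Superposes `mobile` onto `reference` by the Kabsch algorithm on the
#' selected atoms (all alpha carbons by default), applies the transform to
#' every atom of `mobile`, and reports the RMS deviation over the selection
#' (the CaRMS for the default selection). Atoms are matched by chain, residue
#' number and atom name.
#'
#' @param reference,mobile [structure_model()]s sharing topology on the
#'   matched atoms.
#' @param selection `"calpha"`, `"backbone"` or `"all"`.
#' @return A list: `model` (transformed mobile), `rotation` (3 x 3 matrix),
#'   `translation` (length-3 vector; the transform is `x %*% R + t`), `rms`
#'   (Angstrom over the selection) and `n_atoms`.
#' @export
superpose <- function(reference, mobile, selection = c("calpha", "backbone", "all")) {
  selection <- match.arg(selection)
  m <- match_atoms(reference, mobile)
  keep <- switch(selection,
                 calpha = reference$elety[m$.ref_row] == "CA",
                 backbone = reference$elety[m$.ref_row] %in% c("N", "CA", "C", "O"),
                 all = rep(TRUE, nrow(m)))
  m_sel <- m[keep, , drop = FALSE]
  if (nrow(m_sel) < 3L) {
    abort("need at least 3 matched atoms for superposition",
          class = "gabrisk_bad_structure")
  }
  P <- as.matrix(mobile[m_sel$.mob_row, c("x", "y", "z")])    # moving
  Q <- as.matrix(reference[m_sel$.ref_row, c("x", "y", "z")]) # fixed
  pc <- colMeans(P); qc <- colMeans(Q)
  H <- crossprod(sweep(P, 2, pc), sweep(Q, 2, qc))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  trans <- qc - as.numeric(pc %*% R)
  new_xyz <- sweep(as.matrix(mobile[, c("x", "y", "z")]) %*% R, 2, trans, `+`)
  out <- mobile
  out$x <- new_xyz[, 1]; out$y <- new_xyz[, 2]; out$z <- new_xyz[, 3]
  fitted_sel <- new_xyz[m_sel$.mob_row, , drop = FALSE]
  rms <- sqrt(mean(rowSums((fitted_sel - Q)^2)))
  list(model = out, rotation = R, translation = trans,
       rms = rms, n_atoms = nrow(m_sel))
}

#' Per-element side-chain and secondary-structure RMS deviation
#'
#' For each named structural element, the RMS deviation between a reference
#' model and an (already superposed) ensemble member is computed separately
#' over side-chain heavy atoms (everything except N, CA, C, O and hydrogens)
#' and over backbone heavy atoms (N, CA, C, O). Elements whose residues
#' carry no side-chain atoms (glycine-only) report `NA` for the side-chain
#' RMS rather than zero.
#'
#' @param reference a [structure_model()].
#' @param member a superposed [structure_model()] sharing topology with the
#'   reference on scored residues.
#' @param element_map per-residue map (`chain`, `resno`, `element`); defaults
#'   to the reference's attached map.
#' @return A tibble: `chain`, `element`, `sidechain_rms`,
#'   `secondary_structure_rms`, `n_sidechain_atoms`, `n_backbone_atoms`.
#' @export
element_rms <- function(reference, member, element_map = NULL) {
  element_map <- element_map %||% attr(reference, "element_map")
  if (is.null(element_map)) {
    abort("no element map supplied or attached to the reference",
          class = "gabrisk_bad_structure")
  }
  m <- match_atoms(reference, member)
  scored_ref <- dplyr::semi_join(
    tibble(chain = reference$chain, resno = reference$resno,
           elety = reference$elety),
    element_map, by = c("chain", "resno"))
  if (nrow(dplyr::semi_join(scored_ref,
                            tibble(chain = reference$chain[m$.ref_row],
                                   resno = reference$resno[m$.ref_row],
                                   elety = reference$elety[m$.ref_row]),
                            by = c("chain", "resno", "elety"))) < nrow(scored_ref)) {
    abort("topology mismatch: member is missing scored atoms of the reference",
          class = "gabrisk_bad_structure")
  }
  d2 <- rowSums((as.matrix(reference[m$.ref_row, c("x", "y", "z")]) -
                   as.matrix(member[m$.mob_row, c("x", "y", "z")]))^2)
  per_atom <- tibble(
    chain = reference$chain[m$.ref_row],
    resno = reference$resno[m$.ref_row],
    elety = reference$elety[m$.ref_row],
    d2 = d2
  ) |>
    dplyr::filter(!grepl("^[0-9]*H", .data$elety)) |>
    dplyr::inner_join(as_tibble(element_map), by = c("chain", "resno")) |>
    mutate(backbone = .data$elety %in% c("N", "CA", "C", "O"))
  per_atom |>
    group_by(.data$chain, .data$element) |>
    summarise(
      sidechain_rms = if (any(!.data$backbone))
        sqrt(mean(.data$d2[!.data$backbone])) else NA_real_,
      secondary_structure_rms = if (any(.data$backbone))
        sqrt(mean(.data$d2[.data$backbone])) else NA_real_,
      n_sidechain_atoms = sum(!.data$backbone),
      n_backbone_atoms = sum(.data$backbone),
      .groups = "drop"
    )
}

#' Average perturbation over the lowest-energy ensemble members
#'
#' Selects the `n_lowest` lowest-energy members of an ensemble, superposes
#' each onto the reference by a single global Calpha fit, computes
#' [element_rms()] per member, averages each element's RMS across members,
#' and flags elements whose mean side-chain or secondary-structure RMS
#' reaches `threshold`. If the ensemble holds fewer members than `n_lowest`,
#' all members are used and a warning is recorded in the report.
#'
#' @param ensemble a `structure_ensemble` (see
#'   [generate_structure_fixture()]) or a list with `reference`, `members`
#'   (list of [structure_model()]s with `energy` attributes) and optionally
#'   `mutated_site`.
#' @param n_lowest number of lowest-energy members to average over.
#' @param threshold flagging threshold in Angstrom.
#' @return A tibble of class `perturbation_report` (one row per chain x
#'   element with mean RMS values and a `flagged` column), with attributes
#'   `threshold`, `n_used`, `mutated_site` and `warning`.
#' @export
ensemble_rms <- function(ensemble, n_lowest = 10, threshold = 0.5) {
  reference <- ensemble$reference
  members <- ensemble$members
  if (!length(members)) {
    abort("ensemble has no members", class = "gabrisk_bad_structure")
  }
  energies <- vapply(members, function(m) attr(m, "energy"), numeric(1))
  if (any(!is.finite(energies))) {
    abort("every ensemble member needs a finite energy",
          class = "gabrisk_bad_structure")
  }
  warn_msg <- NULL
  if (length(members) < n_lowest) {
    warn_msg <- sprintf("only %d members available; using all (asked for %d)",
                        length(members), n_lowest)
    warn(warn_msg)
    n_lowest <- length(members)
  }
  use <- order(energies)[seq_len(n_lowest)]
  per_member <- purrr::map(members[use], function(m) {
    fitted <- superpose(reference, m, selection = "calpha")$model
    element_rms(reference, fitted)
  })
  report <- bind_rows(per_member) |>
    group_by(.data$chain, .data$element) |>
    summarise(
      sidechain_rms = mean(.data$sidechain_rms),
      secondary_structure_rms = mean(.data$secondary_structure_rms),
      n_sidechain_atoms = .data$n_sidechain_atoms[1],
      n_backbone_atoms = .data$n_backbone_atoms[1],
      .groups = "drop"
    ) |>
    mutate(flagged = (!is.na(.data$sidechain_rms) &
                        .data$sidechain_rms >= threshold) |
             (!is.na(.data$secondary_structure_rms) &
                .data$secondary_structure_rms >= threshold))
  class(report) <- c("perturbation_report", class(report))
  attr(report, "threshold") <- threshold
  attr(report, "n_used") <- n_lowest
  attr(report, "mutated_site") <- ensemble$mutated_site
  attr(report, "warning") <- warn_msg
  report
}

#' Classify a perturbation as local or global
#'
#' A perturbation is `"local"` when every flagged element belongs to the
#' mutated subunit (chain), `"global"` when any flagged element lies in
#' another subunit, and `"none"` when no element is flagged.
#'
#' @param report a `perturbation_report` from [ensemble_rms()].
#' @param mutated_site list or vector whose first entry is the mutated
#'   chain id; defaults to the site recorded on the report.
#' @return `"local"`, `"global"` or `"none"`.
#' @export
classify_perturbation <- function(report, mutated_site = NULL) {
  mutated_site <- mutated_site %||% attr(report, "mutated_site")
  if (is.null(mutated_site)) {
    abort("no mutated site recorded or supplied", class = "gabrisk_bad_input")
  }
  chain <- if (is.list(mutated_site)) mutated_site$chain else mutated_site[[1]]
  flagged <- report$chain[report$flagged]
  if (!length(flagged)) return("none")
  if (all(flagged == chain)) "local" else "global"
}
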