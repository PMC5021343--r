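#' Simulate a concentration-response dataset
#'
#' Applies a long (default 4 s) pulse of each GABA concentration to the
#' scheme, measures the peak current magnitude of each replicate, and returns
#' a tidy table. The deterministic part of every trace depends only on the
#' scheme and protocol; replicate-to-replicate variation is recording noise.
#'
#' @param scheme a [kinetic_scheme()].
#' @param concentrations GABA concentrations in molar (>= 4 values spanning
#'   the response range).
#' @param replicates replicate cells per concentration.
#' @param noise_sd recording noise SD, pA.
#' @param seed integer seed; the table is identical on re-run.
#' @param pulse_duration pulse length, ms.
#' @param sample_rate_khz sampling rate, kHz.
#' @return A tibble: `concentration_M`, `replicate`, `peak_pA`, `response`
#'   (peak normalized to the largest mean peak across concentrations).
#' @export
generate_crc_dataset <- function(scheme, concentrations, replicates = 1,
                                 noise_sd = 0, seed = 1L,
                                 pulse_duration = 4000,
                                 sample_rate_khz = 10) {
  if (!length(concentrations)) {
    abort("`concentrations` must not be empty", class = "gabrisk_bad_input")
  }
  if (length(unique(concentrations)) < 4L) {
    abort("need >= 4 distinct concentrations spanning the response range",
          class = "gabrisk_bad_input")
  }
  concentrations <- sort(concentrations)
  rows <- withr_seed(seed, {
    purrr::map_dfr(seq_along(concentrations), function(i) {
      proto <- stimulus_protocol(gaba_concentration = concentrations[i],
                                 pulse_duration = pulse_duration,
                                 sample_rate_khz = sample_rate_khz)
      tr <- simulate_current(scheme, proto, noise_sd = 0)
      purrr::map_dfr(seq_len(replicates), function(r) {
        noisy <- tr
        if (noise_sd > 0) {
          noisy$current_pA <- tr$current_pA +
            rnorm(nrow(tr), sd = noise_sd)
        }
        tibble(concentration_M = concentrations[i], replicate = r,
               peak_pA = trace_peak(noisy)$peak_magnitude)
      })
    })
  })
  top <- max(tapply(rows$peak_pA, rows$concentration_M, mean))
  mutate(rows, response = .data$peak_pA / top)
}

gabr_genes <- c("GABRA1", "GABRA4", "GABRA5", "GABRA6", "GABRB1", "GABRB2",
                "GABRB3", "GABRG1", "GABRG2", "GABRG3")

#' Generate a variant catalog with a requested cross-classification
#'
#' Expands a per-group specification into individual variant records whose
#' cross-classification (e.g. deleterious x reduced-current, domain x gating
#' defect) matches the requested counts exactly. Genes, substitutions and
#' in-silico scores are synthesized deterministically under the seed; scores
#' are drawn inside the range conventional for each PolyPhen-2 category.
#'
#' @param spec data frame with a count column `n` and any of
#'   `phenotype_group` (`"GEC"`, `"ESP"`, `"control"`), `polyphen_category`
#'   (`"benign"`, `"possibly"`, `"damaging"`), `domain` (`"SP"`, `"NT"`,
#'   `"CL"`, `"TM"`), `reduced_current`, `gating_defect` (logical),
#'   `interface_side`, `gene`, `occurrence`.
#' @param seed integer seed.
#' @return A tibble of variant records (see [read_catalog()] for columns).
#' @export
#' @examples
#' generate_catalog(data.frame(n = c(2, 3), domain = c("NT", "TM"),
#'                             gating_defect = c(TRUE, FALSE)), seed = 1)
generate_catalog <- function(spec, seed = 1L) {
  spec <- as_tibble(spec)
  if (nrow(spec) == 0L) return(empty_catalog())
  if (!"n" %in% names(spec)) {
    abort("`spec` needs a count column `n`", class = "gabrisk_bad_input")
  }
  if (any(!is.finite(spec$n)) || any(spec$n < 0) || any(spec$n != round(spec$n))) {
    abort("inconsistent marginals: counts must be non-negative integers",
          class = "gabrisk_bad_input")
  }
  defaults <- list(phenotype_group = "GEC", polyphen_category = "benign",
                   domain = "NT", reduced_current = FALSE,
                   gating_defect = FALSE, interface_side = "none",
                   gene = NA_character_, occurrence = 1L)
  for (nm in names(defaults)) {
    if (!nm %in% names(spec)) spec[[nm]] <- defaults[[nm]]
  }
  if (!all(spec$domain %in% c("SP", "NT", "CL", "TM"))) {
    abort("domains must be drawn from SP, NT, CL, TM",
          class = "gabrisk_bad_input")
  }
  if (!all(spec$polyphen_category %in% c("benign", "possibly", "damaging"))) {
    abort("unknown PolyPhen-2 category", class = "gabrisk_bad_input")
  }
  rows <- tidyr::uncount(spec, weights = .data$n)
  n_tot <- nrow(rows)
  if (n_tot == 0L) return(empty_catalog())
  withr_seed(seed, {
    rows$gene <- ifelse(is.na(rows$gene),
                        gabr_genes[(seq_len(n_tot) - 1L) %% length(gabr_genes) + 1L],
                        rows$gene)
    aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
    pos <- sample(5:450, n_tot, replace = TRUE)
    wt_aa <- sample(aa, n_tot, replace = TRUE)
    mut_aa <- vapply(wt_aa, function(w) sample(setdiff(aa, w), 1), character(1))
    score_lo <- c(benign = 0, possibly = 0.4, damaging = 0.9)
    score_hi <- c(benign = 0.2, possibly = 0.6, damaging = 1)
    hd <- runif(n_tot, score_lo[rows$polyphen_category],
                score_hi[rows$polyphen_category])
    hv <- pmin(pmax(hd + runif(n_tot, -0.05, 0.05), 0), 1)
    tibble(gene = rows$gene,
           variant = paste0(wt_aa, pos, mut_aa),
           phenotype_group = rows$phenotype_group,
           polyphen_category = rows$polyphen_category,
           humdiv_score = round(hd, 3),
           humvar_score = round(hv, 3),
           domain = rows$domain,
           interface_side = rows$interface_side,
           occurrence = as.integer(rows$occurrence),
           allele_frequency = round(runif(n_tot, 1e-4, 4.9e-3), 5),
           reduced_current = rows$reduced_current,
           gating_defect = rows$gating_defect)
  })
}

empty_catalog <- function() {
  tibble(gene = character(), variant = character(),
         phenotype_group = character(), polyphen_category = character(),
         humdiv_score = numeric(), humvar_score = numeric(),
         domain = character(), interface_side = character(),
         occurrence = integer(), allele_frequency = numeric(),
         reduced_current = logical(), gating_defect = logical())
}

#' Generate a synthetic structure ensemble fixture
#'
#' Builds a toy pentamer-like reference model (`n_subunits` chains, 30
#' residues each with backbone N/CA/C/O and side-chain CB/CG atoms, annotated
#' with three elements per chain: "loop C", "Cys-loop", "M2") plus an
#' ensemble of members in which the side-chain atoms of the listed elements
#' are rigidly displaced by `displacement` Angstrom (along +x), with optional
#' seed-controlled Gaussian jitter on all member atoms. Member energies are
#' `1, 2, ..., ensemble_size` so that which members carry the displacement
#' can be controlled relative to the energy ranking via `perturb_members`.
#'
#' These fixtures are synthetic stand-ins for conformational-sampling output
#' (e.g. Backrub ensembles); they exercise the scoring pipeline, not any
#' physical model.
#'
#' @param n_subunits number of chains (default 5).
#' @param perturbed_elements data frame with `chain` and `element` naming the
#'   displaced elements, or character vector `"A:loop C"` style; `NULL` for
#'   an unperturbed ensemble.
#' @param displacement rigid side-chain displacement, Angstrom (>= 0).
#' @param ensemble_size number of members (>= 1).
#' @param jitter_sd Gaussian jitter SD applied to all member atoms, Angstrom.
#' @param perturb_members indices (in energy order, 1 = lowest) of members to
#'   displace; default all.
#' @param mutated_site list(chain =, resno =); defaults to residue 15 of the
#'   first perturbed element's chain (or chain "A").
#' @param seed integer seed controlling the jitter.
#' @return A list of class `structure_ensemble`: `reference`, `members`
#'   (each with an `energy` attribute), `energies`, `mutated_site`.
#' @export
generate_structure_fixture <- function(n_subunits = 5,
                                       perturbed_elements = NULL,
                                       displacement = 1,
                                       ensemble_size = 20,
                                       jitter_sd = 0,
                                       perturb_members = NULL,
                                       mutated_site = NULL,
                                       seed = 1L) {
  if (displacement < 0) abort("`displacement` must be >= 0", class = "gabrisk_bad_input")
  if (ensemble_size < 1) abort("`ensemble_size` must be >= 1", class = "gabrisk_bad_input")
  chains <- LETTERS[seq_len(n_subunits)]
  elements <- c("loop C", "Cys-loop", "M2")
  emap <- element_map_from_ranges(
    tidyr::crossing(chain = chains,
                    tibble(element = elements,
                           start = c(1, 11, 21), end = c(10, 20, 30))))
  ref_atoms <- purrr::map_dfr(seq_along(chains), function(ci) {
    ang <- 2 * pi * (ci - 1) / n_subunits
    cx <- 20 * cos(ang); cy <- 20 * sin(ang)
    purrr::map_dfr(1:30, function(r) {
      z <- 3 * r
      tibble(chain = chains[ci], resno = r, resid = "ALA",
             elety = c("N", "CA", "C", "O", "CB", "CG"),
             x = cx + c(-0.5, 0, 0.5, 0.7, 0, 0.3),
             y = cy + c(0.3, 0, -0.3, 0.8, 1.5, 2.4),
             z = z + c(-0.4, 0, 0.4, 0.9, 0.2, 0.5))
    })
  })
  reference <- structure_model(ref_atoms, element_map = emap)

  pert <- normalize_elements(perturbed_elements)
  if (!is.null(pert)) {
    known <- unique(emap[, c("chain", "element")])
    bad <- anti_join(pert, known, by = c("chain", "element"))
    if (nrow(bad)) {
      abort(paste0("element not in model: ",
                   paste(paste0(bad$chain, ":", bad$element), collapse = ", ")),
            class = "gabrisk_bad_input")
    }
  }
  if (is.null(perturb_members)) perturb_members <- seq_len(ensemble_size)

  pert_res <- if (!is.null(pert)) {
    dplyr::inner_join(as_tibble(emap), pert, by = c("chain", "element"))
  } else NULL

  members <- withr_seed(seed, {
    purrr::map(seq_len(ensemble_size), function(i) {
      at <- ref_atoms
      if (!is.null(pert_res) && i %in% perturb_members && displacement > 0) {
        hit <- paste(at$chain, at$resno) %in%
          paste(pert_res$chain, pert_res$resno) &
          !(at$elety %in% c("N", "CA", "C", "O"))
        at$x[hit] <- at$x[hit] + displacement
      }
      if (jitter_sd > 0) {
        at$x <- at$x + rnorm(nrow(at), sd = jitter_sd)
        at$y <- at$y + rnorm(nrow(at), sd = jitter_sd)
        at$z <- at$z + rnorm(nrow(at), sd = jitter_sd)
      }
      structure_model(at, energy = as.numeric(i), element_map = emap)
    })
  })
  if (is.null(mutated_site)) {
    mutated_site <- list(chain = if (!is.null(pert)) pert$chain[1] else "A",
                         resno = 15L)
  }
  structure(list(reference = reference, members = members,
                 energies = as.numeric(seq_len(ensemble_size)),
                 mutated_site = mutated_site),
            class = "structure_ensemble")
}

normalize_elements <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    parts <- strsplit(x, ":", fixed = TRUE)
    return(tibble(chain = vapply(parts, `[`, "", 1),
                  element = vapply(parts, `[`, "", 2)))
  }
  as_tibble(x)[, c("chain", "element")]
}
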