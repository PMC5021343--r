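#' Read a GABR variant catalog
#'
#' Reads a TSV/CSV variant catalog and validates it into the standard record
#' layout. Required columns: `gene`, `variant`, `phenotype_group`,
#' `polyphen_category`, `humdiv_score`, `humvar_score`, `domain`,
#' `reduced_current`, `gating_defect`. Optional: `interface_side`,
#' `occurrence`, `allele_frequency`. Functional flags may be logical or
#' `"yes"`/`"no"`. Domain codes outside SP/NT/CL/TM are rejected with the
#' offending row.
#'
#' Two catalogs are packaged under `extdata`: the 32 functionally
#' characterized variants with in-silico scores, domains and functional
#' flags (`gabr_functional_catalog()`), and the 24 unique case-cohort
#' variants with their occurrence counts (`gec_unique_catalog()`).
#'
#' @param path path to a delimited catalog file (TSV unless the extension is
#'   `.csv`).
#' @return A tibble of variant records.
#' @export
read_catalog <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L) return(empty_catalog())
  required <- c("gene", "variant", "phenotype_group", "polyphen_category",
                "humdiv_score", "humvar_score", "domain",
                "reduced_current", "gating_defect")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    abort(paste0("catalog is missing required column(s): ",
                 paste(miss, collapse = ", ")),
          class = "gabrisk_bad_catalog")
  }
  bad <- which(!df$domain %in% c("SP", "NT", "CL", "TM"))
  if (length(bad)) {
    abort(paste0("unknown domain code ", df$domain[bad[1]], " in row ", bad[1],
                 " (expected SP, NT, CL or TM)"),
          class = "gabrisk_bad_catalog")
  }
  bad_cat <- which(!df$polyphen_category %in% c("benign", "possibly", "damaging"))
  if (length(bad_cat)) {
    abort(paste0("unknown PolyPhen-2 category in row ", bad_cat[1]),
          class = "gabrisk_bad_catalog")
  }
  df$reduced_current <- as_flag(df$reduced_current)
  df$gating_defect <- as_flag(df$gating_defect)
  if (!"interface_side" %in% names(df)) df$interface_side <- "none"
  if (!"occurrence" %in% names(df)) df$occurrence <- 1L
  if (!"allele_frequency" %in% names(df)) df$allele_frequency <- NA_real_
  as_tibble(df)
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("yes", "true", "1")
}

#' @rdname read_catalog
#' @export
gabr_functional_catalog <- function() {
  read_catalog(system.file("extdata", "gabr_functional_variants.tsv",
                           package = "gabrisk", mustWork = TRUE))
}

#' @rdname read_catalog
#' @export
gec_unique_catalog <- function() {
  readr::read_tsv(system.file("extdata", "gec_unique_variants.tsv",
                              package = "gabrisk", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' Variants present in exactly one of two cohorts
#'
#' Variants are identified by their (gene, protein substitution) key; a
#' variant is "unique" to a cohort when its key is absent from the other
#' cohort, mirroring the mutually-exclusive definition used for case/control
#' rare-variant comparisons.
#'
#' @param case_records,control_records data frames with `gene` and `variant`
#'   columns.
#' @return A list with `case_unique` and `control_unique`, each a tibble of
#'   distinct keys, plus `shared`.
#' @export
unique_variants <- function(case_records, control_records) {
  key <- c("gene", "variant")
  ca <- dplyr::distinct(as_tibble(case_records)[key])
  co <- dplyr::distinct(as_tibble(control_records)[key])
  list(case_unique = anti_join(ca, co, by = key),
       control_unique = anti_join(co, ca, by = key),
       shared = semi_join(ca, co, by = key))
}

#' Keep rare variants
#'
#' Retains records with `allele_frequency` strictly below `max_frequency`
#' (the conventional rarity cut is < 0.5%).
#'
#' @param records variant records with an `allele_frequency` column.
#' @param max_frequency exclusive upper bound on allele frequency.
#' @return Filtered records.
#' @export
filter_rare <- function(records, max_frequency = 0.005) {
  stopifnot("allele_frequency" %in% names(records))
  dplyr::filter(records, .data$allele_frequency < max_frequency)
}

#' Summarize variant occurrences
#'
#' @param records variant records; an `occurrence` column gives per-variant
#'   occurrence counts (default 1).
#' @return A one-row tibble with `total_occurrences`, `distinct_variants`
#'   and `distinct_genes`; per-gene counts are attached as attribute
#'   `"per_gene"` (a tibble `gene`, `variants`, `occurrences`).
#' @export
#' @examples
#' summarize_occurrences(gec_unique_catalog())
summarize_occurrences <- function(records) {
  records <- as_tibble(records)
  occ <- if ("occurrence" %in% names(records)) records$occurrence else
    rep(1L, nrow(records))
  per_gene <- records |>
    mutate(.occ = occ) |>
    group_by(.data$gene) |>
    summarise(variants = dplyr::n_distinct(.data$variant),
              occurrences = sum(.data$.occ), .groups = "drop")
  out <- tibble(
    total_occurrences = sum(occ),
    distinct_variants = nrow(dplyr::distinct(records[c("gene", "variant")])),
    distinct_genes = dplyr::n_distinct(records$gene)
  )
  attr(out, "per_gene") <- per_gene
  out
}

round_half_up <- function(x) floor(x + 0.5)

#' Distribution of variants across receptor domains
#'
#' Counts records per structural domain and reports integer percentages
#' rounded half-up (so 12.5% prints as 13%).
#'
#' @param records variant records with a `domain` column.
#' @return A tibble: `domain`, `n`, `percent`.
#' @export
#' @examples
#' domain_distribution(gabr_functional_catalog())
domain_distribution <- function(records) {
  stopifnot("domain" %in% names(records))
  if (any(is.na(records$domain))) {
    abort("every record needs a domain", class = "gabrisk_bad_input")
  }
  records |>
    count(.data$domain) |>
    mutate(percent = round_half_up(100 * .data$n / sum(.data$n))) |>
    arrange(dplyr::desc(.data$n))
}

#' Normalize flow-cytometry expression to wild type
#'
#' Net fluorescence intensity is the sample mean FI minus the mock
#' (empty-vector) mean FI; the relative FI normalizes this net FI to the
#' wild-type net FI: `(mean_fi - mock_fi) / wt_net_fi`.
#'
#' @param data data frame with columns `mean_fi`, `mock_fi`, `wt_net_fi`, or
#'   a numeric vector of sample mean FIs.
#' @param mock_fi,wt_net_fi numerics, used when `data` is a vector.
#' @return The input data frame with a `relative_fi` column, or a numeric
#'   vector of relative FIs.
#' @export
#' @examples
#' normalize_expression(110, 10, 100) # 1
normalize_expression <- function(data, mock_fi = NULL, wt_net_fi = NULL) {
  if (is.data.frame(data)) {
    stopifnot(all(c("mean_fi", "mock_fi", "wt_net_fi") %in% names(data)))
    if (any(data$wt_net_fi <= 0)) {
      abort("`wt_net_fi` must be > 0", class = "gabrisk_bad_input")
    }
    return(mutate(as_tibble(data),
                  relative_fi = (.data$mean_fi - .data$mock_fi) / .data$wt_net_fi))
  }
  if (any(wt_net_fi <= 0)) {
    abort("`wt_net_fi` must be > 0", class = "gabrisk_bad_input")
  }
  (data - mock_fi) / wt_net_fi
}
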