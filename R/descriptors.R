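#' Fauchere-Pliska hydrophobicity scale
#'
#' Per-residue hydrophobicity values (octanol/water partition, dimensionless)
#' on the Fauchere-Pliska scale, the scale used by the HeliQuest server.
#' Returned as a named numeric vector over the 20 canonical one-letter codes.
#'
#' @return Named numeric vector of length 20.
#' @examples
#' fauchere_pliska()[["W"]]
#' @export
fauchere_pliska <- function() {
  c(A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
    Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
    L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
    S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22)
}

# split a sequence into residues and validate against the canonical alphabet,
# naming the first offending position on failure
.residues <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L)
    abort("`sequence` must be a single non-empty string of one-letter codes.")
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!res %in% names(fauchere_pliska()))
  if (length(bad))
    abort(sprintf("unknown residue code '%s' at position %d", res[bad[1]], bad[1]))
  res
}

#' Mean per-residue hydrophobicity
#'
#' Arithmetic mean of the Fauchere-Pliska scale values over all residues,
#' the HeliQuest hydrophobicity H. Values are stored at full precision;
#' round only for display.
#'
#' @param sequence One-letter amino-acid string.
#' @return Dimensionless mean hydrophobicity.
#' @examples
#' mean_hydrophobicity("RRRRRRWWWWVV") # 0.448 to 3 d.p.
#' @export
mean_hydrophobicity <- function(sequence) {
  res <- .residues(sequence)
  mean(fauchere_pliska()[res])
}

#' Net charge at neutral pH
#'
#' Integer counting convention: +1 per Arg or Lys, -1 per Asp or Glu,
#' His neutral, termini uncharged. This is the convention under which the
#' charges of Arg/Trp-rich designed peptides equal their arginine counts.
#'
#' @param sequence One-letter amino-acid string.
#' @param pH Retained for interface clarity; only the pH 7 counting rule is
#'   implemented and other values are rejected.
#' @return Signed integer charge (e).
#' @examples
#' net_charge("RRRRRRWWWWVV") # +6
#' @export
net_charge <- function(sequence, pH = 7) {
  if (!identical(as.numeric(pH), 7)) {
    abort("only the fixed pH 7 integer-counting rule is implemented")
  }
  res <- .residues(sequence)
  sum(res %in% c("R", "K")) - sum(res %in% c("D", "E"))
}

#' Peptide descriptor table
#'
#' Tidy wrapper computing length, net charge and mean hydrophobicity for a
#' set of peptides.
#'
#' @param peptides Data frame with columns `id` and `sequence`.
#' @return Tibble with columns `id`, `sequence`, `n_residues`, `net_charge`,
#'   `hydrophobicity_H`.
#' @examples
#' peptide_descriptors(tibble::tibble(
#'   id = c("LE-53", "LE-55"),
#'   sequence = c("RRRRRRWWWWVV", "RRRRRRRRWWWWVVVV")))
#' @export
peptide_descriptors <- function(peptides) {
  stopifnot(is.data.frame(peptides), all(c("id", "sequence") %in% names(peptides)))
  peptides |>
    as_tibble() |>
    dplyr::mutate(
      n_residues = nchar(.data$sequence),
      net_charge = purrr::map_int(.data$sequence, \(s) as.integer(net_charge(s))),
      hydrophobicity_H = purrr::map_dbl(.data$sequence, mean_hydrophobicity)
    )
}

#' Read peptides from FASTA or two-column TSV
#'
#' @param path File path. FASTA is detected by a leading `>`.
#' @return Tibble with `id` and `sequence` columns.
#' @export
read_peptides <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (startsWith(lines[1], ">")) {
    hdr <- grepl("^>", lines)
    id <- sub("^>\\s*", "", lines[hdr])
    grp <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                   \(x) gsub("\\s", "", paste(x, collapse = "")), character(1))
    tibble(id = id, sequence = unname(seqs))
  } else {
    parts <- strsplit(lines, "\\s+")
    tibble(id = vapply(parts, `[`, character(1), 1L),
           sequence = vapply(parts, `[`, character(1), 2L))
  }
}

#' Propagated standard error of a group mean
#'
#' Combines per-species standard deviations into the standard error of the
#' species-averaged value as sqrt(sum(sigma_i^2))/N.
#'
#' @param per_species_sd Non-negative standard deviations, one per species.
#' @param N Number of species averaged (defaults to the number of SDs).
#' @return Standard error (same units as the SDs).
#' @examples
#' propagate_sem(c(3, 4), 2) # 2.5
#' @export
propagate_sem <- function(per_species_sd, N = length(per_species_sd)) {
  if (N < 1) abort("N must be at least 1")
  if (any(per_species_sd < 0)) abort("standard deviations must be >= 0")
  sqrt(sum(per_species_sd^2)) / N
}

#' MIC group summary
#'
#' Unweighted mean over species-level MIC values with a standard error of
#' the mean. When per-species standard deviations are supplied, the SEM is
#' the quadrature combination sqrt(sum(sigma_i^2))/N; otherwise it is the
#' (N-1) sample SD of the species means over sqrt(N). A single species
#' yields SEM 0 by convention.
#'
#' @param panel Data frame in long form with columns `peptide`, `species`,
#'   `mic` (micromolar) and optionally `sd`.
#' @param peptide Peptide label to summarise.
#' @param species_subset Species labels to include; default all present.
#' @return One-row tibble: `peptide`, `group_mean`, `group_sem`, `n_species`.
#' @examples
#' panel <- tibble::tibble(
#'   peptide = "LE-53",
#'   species = c("PA", "AB", "KP", "EC", "Entbac"),
#'   mic = c(10.7, 3.3, 3.6, 4.8, 6.5))
#' mic_group_mean(panel, "LE-53")
#' @export
mic_group_mean <- function(panel, peptide, species_subset = NULL) {
  stopifnot(is.data.frame(panel), all(c("peptide", "species", "mic") %in% names(panel)))
  rows <- panel[panel$peptide == peptide & is.finite(panel$mic), , drop = FALSE]
  if (!is.null(species_subset)) rows <- rows[rows$species %in% species_subset, , drop = FALSE]
  if (nrow(rows) == 0L) abort("no finite MIC values for the requested peptide/species subset")
  if (any(rows$mic <= 0)) abort("MIC values must be positive")
  n <- nrow(rows)
  m <- mean(rows$mic)
  sem <- if ("sd" %in% names(rows) && all(is.finite(rows$sd))) {
    propagate_sem(rows$sd, n)
  } else if (n > 1L) {
    sd(rows$mic) / sqrt(n)
  } else 0
  tibble(peptide = peptide, group_mean = m, group_sem = sem, n_species = n)
}

#' Summarise a MIC panel by group
#'
#' Applies [mic_group_mean()] to every peptide x group combination.
#'
#' @param panel Long-form MIC tibble with columns `peptide`, `species`,
#'   `mic`, and optionally `group` (e.g. Gram stain class) and `sd`.
#' @return Tibble with one row per peptide (per group when present).
#' @export
mic_summary <- function(panel) {
  stopifnot(is.data.frame(panel))
  keys <- intersect(c("peptide", "group"), names(panel))
  panel |>
    as_tibble() |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(\(d, k) {
      s <- mic_group_mean(dplyr::mutate(d, peptide = "x"), "x")
      s$peptide <- NULL
      s
    }) |>
    dplyr::ungroup()
}

#' Mean residue ellipticity from instrument ellipticity
#'
#' Converts instrument ellipticity (mdeg) to mean residue ellipticity using
#' MRE = epsilon x 10^4 / N. The constant folds in the fixed acquisition
#' conditions (10 micromolar peptide in a 3 mL cell); the conversion is only
#' valid at those conditions.
#'
#' @param epsilon Instrument ellipticity.
#' @param n_residues Number of amino acids (>= 1).
#' @return MRE in deg cm^2 dmol^-1.
#' @examples
#' mre_from_ellipticity(1.2, 12) # 1000
#' @export
mre_from_ellipticity <- function(epsilon, n_residues) {
  if (any(n_residues < 1)) abort("n_residues must be >= 1")
  epsilon * 1e4 / n_residues
}

#' Round half to even at a fixed number of decimals
#'
#' Display-rounding convention used for printed tables; stored values keep
#' full precision. R's `round()` already rounds half to even; this wrapper
#' guards against floating-point representation of exact halves.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_even <- function(x, digits = 1) round(x, digits)
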