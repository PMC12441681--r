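#' Monoisotopic residue masses and physical constants
#'
#' Standard monoisotopic masses (Da) of the 20 canonical amino-acid residues
#' (i.e. amino acid minus water), plus the proton and water masses used for
#' the MALDI \eqn{[M+zH]^{z+}} convention.
#'
#' @format Named numeric vector of length 20.
#' @export
RESIDUE_MASS <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' @rdname RESIDUE_MASS
#' @export
PROTON_MASS <- 1.007276

#' @rdname RESIDUE_MASS
#' @export
WATER_MASS <- 18.010565

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L)
    stop("sequence must be a single non-empty string")
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% names(RESIDUE_MASS))
  if (length(bad))
    stop(sprintf("unknown residue code '%s' at position %d", res[bad[1]], bad[1]))
  res
}

# Normalize a modification spec into a data.frame(label, delta, terminus).
# Accepted forms: NULL, a numeric vector of deltas (terminus "C"), a list of
# lists with $label/$delta/$terminus, a data.frame, or the CSV string encoding
# "label:delta" or "label:delta:terminus" joined by ";".
as_modifications <- function(modifications) {
  empty <- data.frame(label = character(), delta = numeric(),
                      terminus = character(), stringsAsFactors = FALSE)
  if (is.null(modifications) || (is.character(modifications) &&
      length(modifications) == 1L && !nzchar(modifications)))
    return(empty)
  if (is.data.frame(modifications)) {
    if (!all(c("label", "delta") %in% names(modifications)))
      stop("modification data.frame needs columns label and delta")
    if (is.null(modifications$terminus)) modifications$terminus <- "C"
    return(modifications[, c("label", "delta", "terminus")])
  }
  if (is.numeric(modifications)) {
    if (!length(modifications)) return(empty)
    lab <- names(modifications) %||% paste0("mod", seq_along(modifications))
    return(data.frame(label = lab, delta = as.numeric(modifications),
                      terminus = "C", stringsAsFactors = FALSE))
  }
  if (is.character(modifications) && length(modifications) == 1L) {
    parts <- strsplit(modifications, ";", fixed = TRUE)[[1]]
    parts <- trimws(parts[nzchar(trimws(parts))])
    if (!length(parts)) return(empty)
    fields <- strsplit(parts, ":", fixed = TRUE)
    return(data.frame(
      label = vapply(fields, `[`, "", 1L),
      delta = as.numeric(vapply(fields, `[`, "", 2L)),
      terminus = vapply(fields, function(f) if (length(f) >= 3L) f[3L] else "C", ""),
      stringsAsFactors = FALSE))
  }
  if (is.list(modifications)) {
    if (!length(modifications)) return(empty)
    return(data.frame(
      label = vapply(modifications, function(m) as.character(m$label %||% "mod"), ""),
      delta = vapply(modifications, function(m) as.numeric(m$delta), 0),
      terminus = vapply(modifications, function(m) as.character(m$terminus %||% "C"), ""),
      stringsAsFactors = FALSE))
  }
  stop("unrecognized modification specification")
}

#' Monoisotopic m/z of a peptide
#'
#' Computes the monoisotopic \eqn{[M+zH]^{z+}} m/z of a canonical peptide:
#' (sum of residue masses + water + sum of modification mass deltas +
#' z protons) / z.
#'
#' @param sequence one-letter residue string (20 canonical codes).
#' @param modifications modification spec (see [as_modifications()] forms):
#'   e.g. C-terminal amidation as `"amidation:-0.98402"` or
#'   `list(list(label = "amidation", delta = -0.98402, terminus = "C"))`.
#' @param charge positive integer charge state.
#' @return m/z in Da.
#' @examples
#' monoisotopic_mz("GG")                      # 133.06076
#' monoisotopic_mz("G", "amidation:-0.98402") # 75.05528
#' @export
monoisotopic_mz <- function(sequence, modifications = NULL, charge = 1L) {
  res <- check_sequence(sequence)
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge))
    stop("charge must be a positive integer")
  mods <- as_modifications(modifications)
  neutral <- sum(RESIDUE_MASS[res]) + WATER_MASS + sum(mods$delta)
  (neutral + charge * PROTON_MASS) / charge
}

#' Singly charged b/y fragment ions of a peptide
#'
#' b_i is the N-terminal prefix of i residues plus a proton; y_i is the
#' C-terminal suffix of i residues plus water and a proton. N-terminal
#' modifications are applied to b ions only, C-terminal ones to y ions only
#' (and both to the precursor mass).
#'
#' @inheritParams monoisotopic_mz
#' @param series character subset of `c("b", "y")`.
#' @return data.frame with columns `series`, `index`, `mz`, `charge`;
#'   empty for single-residue peptides (no internal cleavage site).
#' @export
fragment_ions <- function(sequence, modifications = NULL,
                          series = c("b", "y")) {
  res <- check_sequence(sequence)
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  mods <- as_modifications(modifications)
  n <- length(res)
  out <- data.frame(series = character(), index = integer(),
                    mz = numeric(), charge = integer())
  if (n < 2L) return(out)
  nterm_delta <- sum(mods$delta[mods$terminus == "N"])
  cterm_delta <- sum(mods$delta[mods$terminus == "C"])
  m <- RESIDUE_MASS[res]
  if ("b" %in% series) {
    bi <- cumsum(m)[seq_len(n - 1L)] + PROTON_MASS + nterm_delta
    out <- rbind(out, data.frame(series = "b", index = seq_len(n - 1L),
                                 mz = unname(bi), charge = 1L))
  }
  if ("y" %in% series) {
    yi <- rev(cumsum(rev(m)))[-1L] + WATER_MASS + PROTON_MASS + cterm_delta
    out <- rbind(out, data.frame(series = "y", index = rev(seq_len(n - 1L)),
                                 mz = unname(yi), charge = 1L))
  }
  rownames(out) <- NULL
  out
}

#' Match observed MS/MS peaks against theoretical b/y ions
#'
#' Greedy one-to-one assignment: candidate (theoretical, observed) pairs
#' within the ppm tolerance are ranked by absolute ppm error (ties broken by
#' lower fragment index), and accepted while both members are still unused.
#'
#' @param observed numeric vector of observed m/z values.
#' @param sequence,modifications peptide definition (see [fragment_ions()]).
#' @param tolerance_ppm matching tolerance in ppm (> 0); default 500 ppm
#'   accommodates reflectron MALDI-TOF fragment accuracy.
#' @return object of class `MatchResult`: list with `pairs` (data.frame:
#'   `observed`, `series`, `index`, `theoretical`, `error_ppm`),
#'   `mean_abs_error_ppm` and `n_matched`.
#' @export
match_fragments <- function(observed, sequence, modifications = NULL,
                            tolerance_ppm = 500) {
  if (!is.numeric(tolerance_ppm) || tolerance_ppm <= 0)
    stop("tolerance_ppm must be > 0")
  theo <- fragment_ions(sequence, modifications)
  if (nrow(theo) == 0L)
    stop("peptide has no internal cleavage sites (too short)")
  pairs <- data.frame(observed = numeric(), series = character(),
                      index = integer(), theoretical = numeric(),
                      error_ppm = numeric())
  if (length(observed)) {
    cand <- expand.grid(t = seq_len(nrow(theo)), o = seq_along(observed))
    err <- (observed[cand$o] - theo$mz[cand$t]) / theo$mz[cand$t] * 1e6
    keep <- abs(err) <= tolerance_ppm
    cand <- cand[keep, , drop = FALSE]
    err <- err[keep]
    ord <- order(abs(err), theo$index[cand$t])
    used_t <- logical(nrow(theo)); used_o <- logical(length(observed))
    for (k in ord) {
      ti <- cand$t[k]; oi <- cand$o[k]
      if (used_t[ti] || used_o[oi]) next
      used_t[ti] <- TRUE; used_o[oi] <- TRUE
      pairs <- rbind(pairs, data.frame(
        observed = observed[oi], series = theo$series[ti],
        index = theo$index[ti], theoretical = theo$mz[ti],
        error_ppm = err[k]))
    }
  }
  structure(list(pairs = pairs,
                 mean_abs_error_ppm = if (nrow(pairs)) mean(abs(pairs$error_ppm)) else NA_real_,
                 n_matched = nrow(pairs),
                 tolerance_ppm = tolerance_ppm),
            class = "MatchResult")
}

#' Construct a validated peptide record
#'
#' @param name short label.
#' @param sequence canonical one-letter residue string.
#' @param modifications modification spec (see [monoisotopic_mz()]).
#' @param charge positive integer.
#' @param target_mz optional expected monoisotopic m/z; must agree with the
#'   computed value within 1e-4 Da. Computed when omitted.
#' @return object of class `PeptideRecord`.
#' @export
peptide_record <- function(name, sequence, modifications = NULL,
                           charge = 1L, target_mz = NULL) {
  mz <- monoisotopic_mz(sequence, modifications, charge)
  if (!is.null(target_mz) && !is.na(target_mz)) {
    if (abs(target_mz - mz) > 1e-4)
      stop(sprintf("target_mz %.5f disagrees with computed %.5f for '%s'",
                   target_mz, mz, name))
  }
  structure(list(name = as.character(name), sequence = sequence,
                 modifications = as_modifications(modifications),
                 charge = as.integer(charge), target_mz = mz),
            class = "PeptideRecord")
}

#' Read a peptide target table from CSV
#'
#' Expected columns: `name`, `sequence`, `modifications` (semicolon-separated
#' `label:delta` or `label:delta:terminus` entries, empty allowed), `charge`,
#' `target_mz` (validated against the computed mass when present). An optional
#' `precursor` column groups gene-related peptides for heatmap ordering.
#'
#' @param path CSV file path.
#' @return list of `PeptideRecord`, with the table as attribute `"table"`.
#' @export
read_peptide_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "sequence")
  if (!all(need %in% names(tab)))
    stop("peptide table needs at least columns: name, sequence")
  if (is.null(tab$modifications)) tab$modifications <- ""
  if (is.null(tab$charge)) tab$charge <- 1L
  recs <- lapply(seq_len(nrow(tab)), function(i)
    peptide_record(tab$name[i], tab$sequence[i], tab$modifications[i],
                   tab$charge[i],
                   if ("target_mz" %in% names(tab)) tab$target_mz[i] else NULL))
  names(recs) <- tab$name
  attr(recs, "table") <- tab
  recs
}

#' @export
print.MatchResult <- function(x, ...) {
  cat(sprintf("MatchResult: %d fragment(s) matched", x$n_matched))
  if (x$n_matched)
    cat(sprintf(", mean |error| = %.1f ppm", x$mean_abs_error_ppm))
  cat(sprintf(" (tolerance %.0f ppm)\n", x$tolerance_ppm))
  if (nrow(x$pairs)) print(x$pairs, ...)
  invisible(x)
}
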