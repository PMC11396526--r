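# Statistical analyses over per-isomer invariant records and externally
# supplied energy tables: Clar-number populations, C-vs-K statistics, the
# Zhang-Ye-Liu stability hypothesis and its Clar-count variant, and the
# ZZ-polynomial uniqueness check.

.HARTREE_TO_KCAL <- 627.5094740631

.label <- function(n, m) sprintf("%d:%d", n, m)

#' Population of isomers by Clar number
#'
#' Histogram of the Clar number over an isomer set, with percentages rounded
#' to integers (half away from zero).  When an energy table is supplied the
#' class containing the minimum-energy isomer is flagged.
#'
#' @param records invariant records (see [isomer_invariants()]).
#' @param energies optional energy table (see [read_energy_table()]).
#' @return data.frame with columns `Cl`, `count`, `percent` and (with
#'   energies) logical `has_min_energy`.
#' @export
clar_population <- function(records, energies = NULL) {
  if (!nrow(records)) {
    return(data.frame(Cl = integer(), count = integer(), percent = integer()))
  }
  tab <- as.data.frame(table(Cl = records$Cl), stringsAsFactors = FALSE)
  names(tab) <- c("Cl", "count")
  tab$Cl <- as.integer(tab$Cl)
  tab$count <- as.integer(tab$count)
  pct <- 100 * tab$count / sum(tab$count)
  tab$percent <- as.integer(sign(pct) * floor(abs(pct) + 0.5))
  if (!is.null(energies)) {
    rk <- rank_by_energy(records, energies)
    best <- rk$data[1, ]
    tab$has_min_energy <- tab$Cl == records$Cl[records$n == best$n &
                                                 records$m == best$m]
  }
  tab
}

#' Clar-count versus Kekule-count statistics
#'
#' Every Clar cover of order 0 is a Kekule structure, so C >= K for every
#' isomer (asserted).  Reports the squared correlation between C and K, the
#' range of the per-isomer C/K ratio (the lower wedge boundary is read as
#' the minimum ratio), and the (K, C) rows for external plotting.
#'
#' @param records invariant records.
#' @return list with `r_squared`, `min_ratio`, `max_ratio`, `data`
#'   (n, m, K, C, Cl, ratio).
#' @export
ck_statistics <- function(records) {
  if (any(records$C < records$K)) {
    stop("invalid records: found C < K, impossible for Clar covers")
  }
  ratio <- records$C / records$K
  r2 <- if (nrow(records) > 1L &&
            stats::sd(records$K) > 0 && stats::sd(records$C) > 0) {
    stats::cor(records$C, records$K)^2
  } else {
    NA_real_
  }
  list(r_squared = r2,
       min_ratio = min(ratio), max_ratio = max(ratio),
       data = data.frame(n = records$n, m = records$m, K = records$K,
                         C = records$C, Cl = records$Cl, ratio = ratio))
}

#' Read a per-isomer energy table
#'
#' TSV with columns n, m, energy, unit; the unit tag must be "hartree" or
#' "kcal/mol".  Duplicate labels are an error.
#'
#' @param path file path.
#' @return data.frame with columns n, m, energy, unit.
#' @export
read_energy_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("n", "m", "energy", "unit")
  if (!all(need %in% names(df))) {
    stop("energy table must have columns: ", paste(need, collapse = ", "))
  }
  .check_energies(df)
  df
}

.check_energies <- function(energies) {
  if (!all(energies$unit %in% c("hartree", "kcal/mol"))) {
    stop("unknown energy unit tag; use 'hartree' or 'kcal/mol'")
  }
  if (any(!is.finite(energies$energy))) stop("non-finite energy value")
  if (anyDuplicated(energies[, c("n", "m")])) {
    stop("duplicate isomer label in energy table")
  }
  invisible(energies)
}

.energy_kcal <- function(energies) {
  ifelse(energies$unit == "hartree",
         energies$energy * .HARTREE_TO_KCAL, energies$energy)
}

#' Rank isomers by energy
#'
#' Stable ascending sort after unit normalization
#' (1 hartree = 627.5094740631 kcal/mol).
#'
#' @param records invariant records (each must have an energy row).
#' @param energies energy table.
#' @return list with `labels` ("n:m", ascending energy) and `data` (merged,
#'   sorted data.frame with `energy_kcal`).
#' @export
rank_by_energy <- function(records, energies) {
  .check_energies(energies)
  energies$energy_kcal <- .energy_kcal(energies)
  merged <- merge(records, energies[, c("n", "m", "energy_kcal")],
                  by = c("n", "m"))
  if (nrow(merged) < nrow(records)) {
    stop("energies missing for ", nrow(records) - nrow(merged), " isomer(s)")
  }
  merged <- merged[order(merged$energy_kcal, merged$n, merged$m), ]
  rownames(merged) <- NULL
  list(labels = .label(merged$n, merged$m), data = merged)
}

.argopt_set <- function(records, col, max = TRUE) {
  v <- records[[col]]
  opt <- if (max) max(v) else min(v)
  .label(records$n[v == opt], records$m[v == opt])
}

.stability_hypothesis <- function(records, energies, count_col) {
  if (is.null(energies)) stop("energy table is required")
  .check_energies(energies)
  maxCl <- max(records$Cl)
  class_recs <- records[records$Cl == maxCl, ]
  candidates <- .argopt_set(class_recs, count_col, max = TRUE)
  rk <- rank_by_energy(records, energies)
  emin <- min(rk$data$energy_kcal)
  most_stable <- .label(rk$data$n[rk$data$energy_kcal == emin],
                        rk$data$m[rk$data$energy_kcal == emin])
  holds <- all(most_stable %in% candidates)
  list(holds = holds,
       verdict = if (holds) "holds" else "fails",
       max_Cl = maxCl,
       candidates = candidates,
       candidate_count = max(class_recs[[count_col]]),
       most_stable = most_stable,
       count_used = count_col)
}

#' The Zhang-Ye-Liu stability hypothesis and its Clar-count variant
#'
#' `zhang_hypothesis` tests whether the most stable isomer (global energy
#' minimum) maximizes the Kekule count K among the isomers with the maximal
#' Clar number Cl; `modified_zhang_hypothesis` replaces K with the Clar
#' count C.  Ties in either optimum are reported as label sets and the
#' verdict holds only when every minimum-energy label is among the
#' candidates.  The verdict is invariant under energy units and any
#' increasing affine transformation of the energies.
#'
#' @param records invariant records for all isomers of one fullerene.
#' @param energies energy table covering all records.
#' @return list with `holds`, `verdict` ("holds"/"fails"), `max_Cl`,
#'   `candidates` (argmax labels), `candidate_count`, `most_stable`
#'   (argmin-energy labels).
#' @export
zhang_hypothesis <- function(records, energies) {
  .stability_hypothesis(records, energies, "K")
}

#' @rdname zhang_hypothesis
#' @export
modified_zhang_hypothesis <- function(records, energies) {
  .stability_hypothesis(records, energies, "C")
}

#' Check uniqueness of ZZ polynomials over an isomer set
#'
#' Groups records by their full coefficient vector and reports collisions;
#' distinct isomers of C20-C70 are expected to have pairwise distinct ZZ
#' polynomials, making the polynomial a label for the isomorphism class.
#'
#' @param records invariant records.
#' @return list with `unique` (logical) and `collisions` (list of label
#'   vectors sharing one polynomial).
#' @export
uniqueness_check <- function(records) {
  if (!nrow(records)) return(list(unique = TRUE, collisions = list()))
  key <- records$coeffs  # the full coefficient vector is the group key
  dup <- unique(key[duplicated(key)])
  collisions <- lapply(dup, function(k) {
    .label(records$n[key == k], records$m[key == k])
  })
  list(unique = length(collisions) == 0L, collisions = collisions)
}
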