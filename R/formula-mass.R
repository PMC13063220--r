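# Exact-mass engine: molecular formulas, adducts, charge, isotopologue m/z.

# Monoisotopic (lightest-isotope) atomic masses in Da, CODATA/AME-derived,
# >= 6 decimals. Versioned constant; no runtime lookup.
.ATOMIC_MASS_VERSION <- "AME2020-subset-1"
.ATOMIC_MASS <- c(
  H  = 1.00782503,
  D  = 2.01410178,   # convenience symbol for 2H
  C  = 12.00000000,
  N  = 14.00307401,
  O  = 15.99491462,
  F  = 18.99840316,
  Na = 22.98976928,
  Mg = 23.98504170,
  Si = 27.97692653,
  P  = 30.97376200,
  S  = 31.97207117,
  Cl = 34.96885268,
  K  = 38.96370649,
  Ca = 39.96259086,
  Fe = 55.93493633,
  Br = 78.91833760,
  I  = 126.90447300
)

#' Electron mass in Da
#' @keywords internal
.ELECTRON_MASS <- 0.00054858

# Mass shift per heavy-isotope substitution, Da.
.ISOTOPE_SHIFT <- c(
  "13C" = 1.00335484,
  "15N" = 0.99703489,
  "2H"  = 1.00627675,
  "18O" = 2.00424638,
  "34S" = 1.99579590
)

#' Parse a molecular formula string
#'
#' Parses Hill-style formulas such as `"C11H12O2"` into a named count vector.
#' Element symbols must exist in the built-in monoisotopic mass table.
#'
#' @param formula A formula string (e.g. `"C11H12O2"`), or an already-parsed
#'   named numeric vector of element counts (returned unchanged after
#'   validation).
#' @return A named integer vector of element counts with class
#'   `"orbiso_formula"`.
#' @examples
#' parse_formula("C11H12O2")
#' @export
parse_formula <- function(formula) {
  if (inherits(formula, "orbiso_formula")) return(formula)
  if (is.numeric(formula) && !is.null(names(formula))) {
    counts <- formula
  } else {
    if (!is.character(formula) || length(formula) != 1L || is.na(formula)) {
      stop("`formula` must be a single formula string, e.g. \"C11H12O2\"")
    }
    s <- gsub("[[:space:]]", "", formula)
    if (!nzchar(s)) stop("empty formula")
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
    toks <- regmatches(s, list(m))[[1]]
    if (sum(nchar(toks)) != nchar(s)) {
      stop("cannot parse formula: ", formula)
    }
    el <- sub("[0-9]*$", "", toks)
    n <- sub("^[A-Za-z]+", "", toks)
    n <- ifelse(nzchar(n), as.integer(n), 1L)
    counts <- tapply(n, el, sum)
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  unknown <- setdiff(names(counts), names(.ATOMIC_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(counts < 0)) stop("negative element count")
  if (sum(counts) == 0) stop("formula has no atoms")
  structure(counts, class = "orbiso_formula")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum over elements of count times the lightest-isotope exact mass.
#'
#' @param formula Formula string or parsed formula (see [parse_formula()]).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C11H12O2") # 176.0837
#' monoisotopic_mass("H2O")      # 18.0106
#' @export
monoisotopic_mass <- function(formula) {
  f <- parse_formula(formula)
  sum(.ATOMIC_MASS[names(f)] * as.numeric(f))
}

#' Define an isotopologue target
#'
#' A target is a neutral molecular formula plus optional heavy-isotope
#' substitutions, an adduct expressed as a signed formula delta (default:
#' deprotonation, i.e. remove one H), and a charge (default -1). The
#' theoretical m/z includes the electron mass: anions gain electrons,
#' cations lose them.
#'
#' @param formula Neutral formula string or parsed formula.
#' @param substitutions Named integer vector of heavy-isotope substitution
#'   counts, e.g. `c("13C" = 1)`. Substituted atoms must exist in the formula.
#' @param adduct_remove,adduct_add Formula strings (or `NULL`) removed from /
#'   added to the neutral molecule before ionization. The default removes one
#'   H ("[M-H]-").
#' @param charge Nonzero signed integer charge (default -1).
#' @param tolerance Match tolerance value (default 5).
#' @param tolerance_unit `"ppm"` (default) or `"da"`.
#' @param label Text label used in outputs.
#' @return An object of class `"orbiso_target"` with the computed
#'   `theoretical_mz`.
#' @examples
#' isotopologue_target("C11H12O2", label = "THN M0")
#' isotopologue_target("C11H12O2", substitutions = c("13C" = 1), label = "THN M+1")
#' @export
isotopologue_target <- function(formula,
                                substitutions = NULL,
                                adduct_remove = "H",
                                adduct_add = NULL,
                                charge = -1L,
                                tolerance = 5,
                                tolerance_unit = c("ppm", "da"),
                                label = NULL) {
  f <- parse_formula(formula)
  tolerance_unit <- match.arg(tolerance_unit)
  if (!is.numeric(charge) || length(charge) != 1L || charge == 0) {
    stop("`charge` must be a nonzero integer")
  }
  if (!is.null(substitutions)) {
    if (is.null(names(substitutions)) ||
        !all(names(substitutions) %in% names(.ISOTOPE_SHIFT))) {
      stop("substitutions must be named with supported isotope labels: ",
           paste(names(.ISOTOPE_SHIFT), collapse = ", "))
    }
    elem <- sub("^[0-9]+", "", names(substitutions))
    # 2H substitution targets H, 13C targets C, etc.
    avail <- stats::setNames(rep(0L, length(elem)), elem)
    have <- names(avail) %in% names(f)
    avail[have] <- as.integer(f[names(avail)[have]])
    if (any(substitutions > avail)) {
      stop("substitution count exceeds atoms available in formula")
    }
    if (any(substitutions < 0)) stop("negative substitution count")
  }
  if (tolerance <= 0) stop("`tolerance` must be > 0")
  tgt <- structure(
    list(formula = f,
         substitutions = substitutions,
         adduct_remove = if (!is.null(adduct_remove)) parse_formula(adduct_remove),
         adduct_add = if (!is.null(adduct_add)) parse_formula(adduct_add),
         charge = as.integer(charge),
         tolerance = tolerance,
         tolerance_unit = tolerance_unit,
         label = label %||% paste0(format_formula(f), " z=", charge)),
    class = "orbiso_target")
  tgt$theoretical_mz <- ion_mz(tgt)
  tgt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

format_formula <- function(f) {
  f <- parse_formula(f)
  paste0(names(f), ifelse(f > 1, as.character(as.integer(f)), ""),
         collapse = "")
}

#' Theoretical m/z of an ion target
#'
#' m/z = (neutral mass + adduct delta + isotope substitution shifts
#' - charge x electron mass) / |charge|. With the default `[M-H]-` adduct the
#' ion gains one electron mass.
#'
#' @param target An `orbiso_target` from [isotopologue_target()].
#' @return m/z in Da (unrounded).
#' @examples
#' round(ion_mz(isotopologue_target("C11H12O2")), 3) # 175.076
#' @export
ion_mz <- function(target) {
  stopifnot(inherits(target, "orbiso_target"))
  if (target$charge == 0) stop("charge must be nonzero")
  m <- monoisotopic_mass(target$formula)
  if (!is.null(target$adduct_remove)) m <- m - monoisotopic_mass(target$adduct_remove)
  if (!is.null(target$adduct_add)) m <- m + monoisotopic_mass(target$adduct_add)
  if (!is.null(target$substitutions)) {
    m <- m + sum(.ISOTOPE_SHIFT[names(target$substitutions)] *
                   as.numeric(target$substitutions))
  }
  (m - target$charge * .ELECTRON_MASS) / abs(target$charge)
}

#' m/z of a heavy-isotopologue of an existing target
#'
#' Convenience wrapper: applies additional substitutions to a target and
#' returns the ion m/z. One 13C substitution shifts the ion by
#' 1.00335484 / |charge| Da, independent of the adduct.
#'
#' @param target An `orbiso_target`.
#' @param substitutions Named substitution counts, default one 13C.
#' @return m/z in Da.
#' @examples
#' t0 <- isotopologue_target("C11H12O2")
#' round(isotopologue_mz(t0), 3) # 176.080
#' @export
isotopologue_mz <- function(target, substitutions = c("13C" = 1)) {
  stopifnot(inherits(target, "orbiso_target"))
  combined <- c(target$substitutions, substitutions)
  combined <- tapply(as.numeric(combined), names(combined), sum)
  combined <- stats::setNames(as.numeric(combined), names(combined))
  t2 <- isotopologue_target(target$formula,
                            substitutions = combined,
                            adduct_remove = if (!is.null(target$adduct_remove))
                              format_formula(target$adduct_remove),
                            adduct_add = if (!is.null(target$adduct_add))
                              format_formula(target$adduct_add),
                            charge = target$charge,
                            tolerance = target$tolerance,
                            tolerance_unit = target$tolerance_unit,
                            label = target$label)
  t2$theoretical_mz
}

#' Absolute match tolerance of a target, in Da, at its theoretical m/z
#' @param target An `orbiso_target`.
#' @return Tolerance half-width in Da.
#' @export
target_tolerance_da <- function(target) {
  stopifnot(inherits(target, "orbiso_target"))
  if (target$tolerance_unit == "da") target$tolerance
  else target$tolerance * 1e-6 * target$theoretical_mz
}

#' @export
print.orbiso_target <- function(x, ...) {
  subs <- if (is.null(x$substitutions)) "none" else
    paste(names(x$substitutions), x$substitutions, sep = "x", collapse = ", ")
  cat(sprintf("<orbiso_target> %s\n  formula: %s  substitutions: %s  charge: %+d\n  theoretical m/z: %.6f  tolerance: %g %s\n",
              x$label, format_formula(x$formula), subs, x$charge,
              x$theoretical_mz, x$tolerance, x$tolerance_unit))
  invisible(x)
}

#' Standard light/heavy target pair for a 13C/12C measurement
#'
#' Builds the monoisotopic (light) and one-13C (heavy) deprotonated targets
#' for a neutral formula — the pair every ratio computation consumes.
#'
#' @inheritParams isotopologue_target
#' @param label_prefix Prefix for the two labels (suffixes " M0" / " M+1").
#' @return List with elements `light` and `heavy` (both `orbiso_target`).
#' @examples
#' target_pair("C11H12O2", label_prefix = "THN")
#' @export
target_pair <- function(formula, adduct_remove = "H", adduct_add = NULL,
                        charge = -1L, tolerance = 5,
                        tolerance_unit = c("ppm", "da"),
                        label_prefix = NULL) {
  tolerance_unit <- match.arg(tolerance_unit)
  pre <- label_prefix %||% format_formula(parse_formula(formula))
  list(
    light = isotopologue_target(formula, NULL, adduct_remove, adduct_add,
                                charge, tolerance, tolerance_unit,
                                paste0(pre, " M0")),
    heavy = isotopologue_target(formula, c("13C" = 1), adduct_remove,
                                adduct_add, charge, tolerance, tolerance_unit,
                                paste0(pre, " M+1"))
  )
}
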