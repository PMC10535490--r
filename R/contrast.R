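#' Specify an H2O/D2O solvent
#'
#' @param d2o_volume_fraction Volume fraction of D2O, 0-1.
#' @param solutes Optional named list of solute molarities (e.g. EDTA, HEPES),
#'   carried as metadata only; millimolar buffer components are negligible for
#'   the scattering-length density.
#' @return An object of class `solvent_spec`.
#' @export
solvent_spec <- function(d2o_volume_fraction, solutes = list()) {
  f <- as.numeric(d2o_volume_fraction)
  if (length(f) != 1 || !is.finite(f) || f < 0 || f > 1)
    stop("d2o_volume_fraction must be a single value in [0, 1]")
  structure(list(d2o_volume_fraction = f, solutes = solutes),
            class = "solvent_spec")
}

#' Specify a biomolecular component composition
#'
#' Mass-fraction recipe over biomolecular classes, with a deuteration level
#' for non-labile hydrogens, from which solvent-dependent scattering-length
#' densities and contrast-match points derive. The default composition is the
#' E. coli dry-matter table (protein 15, nucleic acid 7, lipid 2,
#' carbohydrate 3, other organics 1, inorganic 1, % w/w of the wet cell),
#' renormalized over the dry classes.
#'
#' @param mass_fractions Named numeric vector over
#'   `protein, nucleic_acid, lipid, carbohydrate, other_organic, inorganic`
#'   (missing classes are 0); need not sum to 1 (renormalized).
#' @param deuteration_fraction Fraction of non-labile H replaced by D, 0-1.
#' @param v_a Partial specific volume, cm^3/g; must lie in (0.4, 1.2).
#' @return An object of class `component_composition`.
#' @export
#' @examples
#' debris <- component_composition(deuteration_fraction = 0.8)
#' match_point(debris)
component_composition <- function(mass_fractions = c(protein = 15,
                                                     nucleic_acid = 7,
                                                     lipid = 2,
                                                     carbohydrate = 3,
                                                     other_organic = 1,
                                                     inorganic = 1),
                                  deuteration_fraction = 0,
                                  v_a = 0.74) {
  classes <- names(.class_formulas)
  mf <- setNames(numeric(length(classes)), classes)
  if (is.null(names(mass_fractions)) ||
      !all(names(mass_fractions) %in% classes))
    stop("mass_fractions must be named with classes among: ",
         paste(classes, collapse = ", "))
  mf[names(mass_fractions)] <- as.numeric(mass_fractions)
  if (any(mf < 0)) stop("mass fractions must be non-negative")
  if (sum(mf) <= 0) stop("all-zero mass fractions")
  if (deuteration_fraction < 0 || deuteration_fraction > 1)
    stop("deuteration_fraction must be in [0, 1]")
  if (v_a <= 0.4 || v_a >= 1.2) stop("v_a must be in (0.4, 1.2) cm^3/g")
  structure(list(mass_fractions = mf / sum(mf),
                 deuteration_fraction = deuteration_fraction, v_a = v_a),
            class = "component_composition")
}

#' Solvent scattering-length density
#'
#' Linear volume-fraction mix of the pure H2O and D2O SLDs, each computed
#' from tabulated coherent scattering lengths and a 30.0 A^3 molecular
#' volume. Millimolar buffer solutes are ignored.
#'
#' @param spec A [solvent_spec], or a bare D2O volume fraction in \[0, 1\]
#'   (values outside are allowed for extrapolated match-point work).
#' @return SLD in inverse square Angstroms.
#' @export
#' @examples
#' solvent_sld(0)    # H2O, about -0.56e-6
#' solvent_sld(1)    # D2O, about +6.4e-6
solvent_sld <- function(spec) {
  f <- if (inherits(spec, "solvent_spec")) spec$d2o_volume_fraction
       else as.numeric(spec)
  b_h2o <- 2 * .b_coh[["H"]] + .b_coh[["O"]]
  b_d2o <- 2 * .b_coh[["D"]] + .b_coh[["O"]]
  rho_h <- b_h2o * .fm_per_A / .v_water
  rho_d <- b_d2o * .fm_per_A / .v_water
  unname((1 - f) * rho_h + f * rho_d)
}

# per-class SLD at solvent D2O fraction f (may exceed [0,1] for extrapolation)
.class_sld <- function(class, deuteration, f, exchange_efficiency) {
  fm <- .class_formulas[[class]]
  x <- f * exchange_efficiency           # labile-H deuterium occupancy
  b_heavy <- sum(.b_coh[names(fm$counts)] * fm$counts)
  n_nonlab <- fm$h_total - fm$h_labile
  b_h <- .b_coh[["H"]]; b_d <- .b_coh[["D"]]
  b <- b_heavy +
    n_nonlab * ((1 - deuteration) * b_h + deuteration * b_d) +
    fm$h_labile * ((1 - x) * b_h + x * b_d)
  b * .fm_per_A / fm$volume
}

#' Component scattering-length density in a given solvent
#'
#' Volume-weighted SLD over the biomolecular classes, each class using a
#' fixed reference monomer formula, with labile hydrogens exchanged at
#' solvent D2O fraction times the exchange efficiency and non-labile
#' hydrogens deuterated at the composition's deuteration fraction.
#'
#' @param comp A [component_composition].
#' @param solvent A [solvent_spec] or bare D2O fraction (see [solvent_sld]).
#' @param exchange_efficiency Fraction of labile sites that actually
#'   exchange (default 0.9; complete exchange is rarely achieved).
#' @return SLD in inverse square Angstroms.
#' @export
component_sld <- function(comp, solvent, exchange_efficiency = 0.9) {
  stopifnot(inherits(comp, "component_composition"))
  f <- if (inherits(solvent, "solvent_spec")) solvent$d2o_volume_fraction
       else as.numeric(solvent)
  mf <- comp$mass_fractions
  active <- names(mf)[mf > 0]
  slds <- vapply(active, .class_sld, numeric(1),
                 deuteration = comp$deuteration_fraction, f = f,
                 exchange_efficiency = exchange_efficiency)
  # volume weights: mass fraction x specific monomer volume per gram
  vols <- vapply(active, function(cl) {
    fm <- .class_formulas[[cl]]
    fm$volume / fm$mass
  }, numeric(1))
  w <- mf[active] * vols
  unname(sum(w * slds) / sum(w))
}

#' Contrast-match point of a composition
#'
#' Solves for the solvent D2O percentage at which the component SLD equals
#' the solvent SLD (zero contrast). Both SLDs are affine in the D2O
#' fraction, so the crossing is found analytically from two evaluations;
#' match points above 100% D2O are legal extrapolated crossings (deuterated
#' crowders can exceed the pure-D2O SLD).
#'
#' @inheritParams component_sld
#' @return Match point in % D2O (may exceed 100).
#' @export
#' @examples
#' component_composition(c(protein = 1))  |> match_point()  # ~ 42% D2O
match_point <- function(comp, exchange_efficiency = 0.9) {
  s0 <- component_sld(comp, 0, exchange_efficiency) - solvent_sld(0)
  s1 <- component_sld(comp, 1, exchange_efficiency) - solvent_sld(1)
  slope <- s1 - s0
  if (abs(slope) < 1e-16) stop("contrast does not vary with D2O fraction")
  f <- -s0 / slope
  if (f < -0.5 || f > 2.0)
    stop("no contrast match within [-50, 200]% D2O (unmatched contrast)")
  100 * f
}

#' Match point of a volume mixture of two components
#'
#' The match point is linear in SLD, which is linear in the mixing volume
#' fraction, so the mixture match point is the volume-weighted mean. This is
#' the design arithmetic behind culturing cells in deuterated/non-deuterated
#' medium mixtures (e.g. 87/13 v/v) to place the debris match point near
#' 100% D2O.
#'
#' @param mp_a,mp_b Match points of the two components, % D2O.
#' @param vol_ratio_a Volume fraction of component a, 0-1.
#' @return Mixture match point, % D2O.
#' @export
#' @examples
#' mixture_match_point(110, 33, 0.87)  # ~ 100% D2O
mixture_match_point <- function(mp_a, mp_b, vol_ratio_a) {
  if (!is.finite(mp_a) || !is.finite(mp_b)) stop("match points must be finite")
  if (vol_ratio_a < 0 || vol_ratio_a > 1)
    stop("vol_ratio_a must be in [0, 1]")
  vol_ratio_a * mp_a + (1 - vol_ratio_a) * mp_b
}

#' Concentration after volume-parts mixing
#'
#' @param c_stock Stock concentration (any unit, e.g. % w/v).
#' @param vol_parts_stock,vol_parts_other Volume parts of stock and diluent.
#' @return Final concentration in the stock's units.
#' @export
#' @examples
#' dilution(15, 7, 1)  # 15% w/v stock at 7:1 -> 13.125
#' dilution(4, 1, 7)   # 4% w/v stock at 1:7 -> 0.5
dilution <- function(c_stock, vol_parts_stock, vol_parts_other) {
  if (vol_parts_stock <= 0 || vol_parts_other < 0)
    stop("volume parts must be positive (stock) and non-negative (other)")
  c_stock * vol_parts_stock / (vol_parts_stock + vol_parts_other)
}
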