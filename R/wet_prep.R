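# Stoichiometric constants for recipe -> concentration conversion.
# Lugol's 3% w/v is a 1:2 w/v mixture of I2 and KI; only the iodine atoms
# count towards m0 (each I2 contributes two).
.stoich <- list(
  M_I = 126.9,       # g/mol, iodine (atomic)
  M_KI = 166,        # g/mol, potassium iodide
  M_vitC = 176.12,   # g/mol, ascorbic acid
  lugol_I2_g_per_100ml = 1,
  lugol_KI_g_per_100ml = 2
)

#' Iodine content of Lugol's 3% solution
#'
#' Grams of iodine (as I atoms, counting both the I2 and the KI component)
#' per 100 ml of Lugol's 3% w/v: `1 + 2 * 126.9/166`, reported rounded to
#' 5 significant figures (2.5289 g/100 ml). The rounded value is the one
#' used throughout recipe conversion, so tabulated concentrations derived
#' from it reproduce exactly.
#'
#' @param i2_g_per_100ml,ki_g_per_100ml Grams of I2 and KI per 100 ml
#'   (defaults: the 1:2 w/v formulation).
#' @return Grams of iodine atoms per 100 ml (5 significant figures).
#' @examples
#' lugol_iodine_content()                      # 2.5289
#' lugol_iodine_content(ki_g_per_100ml = 0)    # 1: only I2 contributes
#' @export
lugol_iodine_content <- function(i2_g_per_100ml = .stoich$lugol_I2_g_per_100ml,
                                 ki_g_per_100ml = .stoich$lugol_KI_g_per_100ml) {
  check_number(i2_g_per_100ml, "i2_g_per_100ml", lower = 0)
  check_number(ki_g_per_100ml, "ki_g_per_100ml", lower = 0)
  signif(i2_g_per_100ml + ki_g_per_100ml * .stoich$M_I / .stoich$M_KI, 5)
}

#' Vitamin C stock solution concentration
#'
#' Molar concentration of a stock made by dissolving a vitamin C tablet in
#' water: `(tablet_mg / 1000 / 176.12) / (dilution_ml / 1000)` mol/l.
#'
#' @param tablet_mg Tablet mass in mg (>= 0).
#' @param dilution_ml Dilution volume in ml (> 0).
#' @return Stock concentration in mol/l.
#' @examples
#' vitc_stock_concentration(1000, 30)    # 0.18926 mol/l
#' vitc_stock_concentration(1000, 120)   # 0.04731 mol/l
#' @export
vitc_stock_concentration <- function(tablet_mg, dilution_ml) {
  check_number(tablet_mg, "tablet_mg", lower = 0)
  check_number(dilution_ml, "dilution_ml", lower = 0, strict = TRUE)
  (tablet_mg / 1000 / .stoich$M_vitC) / (dilution_ml / 1000)
}

#' Kitchen-measure recipe for one clock experiment
#'
#' Describes one experimental condition the way it is mixed at the bench:
#' a vitamin C stock (tablet + dilution), an aliquot of that stock, Lugol's
#' 3% iodine, water, and 3% hydrogen peroxide (held in excess; it enters
#' only the total volume).
#'
#' @param vitc_tablet_mg Vitamin C tablet mass, mg.
#' @param vitc_dilution_ml Stock dilution volume, ml.
#' @param stock_aliquot_ml Stock volume used, ml (bench protocol: 5).
#' @param lugol_ml Lugol's 3% w/v volume, ml.
#' @param water_ml Total added water, ml (bench protocol: 60 + 60 = 120).
#' @param peroxide_ml 3% hydrogen peroxide volume, ml (bench protocol: 15).
#' @return An object of class `clock_recipe`.
#' @export
recipe <- function(vitc_tablet_mg = 1000, vitc_dilution_ml = 60,
                   stock_aliquot_ml = 5, lugol_ml = 5,
                   water_ml = 120, peroxide_ml = 15) {
  check_number(vitc_tablet_mg, "vitc_tablet_mg", lower = 0, strict = TRUE)
  for (nm in c("vitc_dilution_ml", "stock_aliquot_ml", "water_ml",
               "peroxide_ml"))
    check_number(get(nm), nm, lower = 0, strict = TRUE)
  check_number(lugol_ml, "lugol_ml", lower = 0)  # 0 allowed: an iodine-free mix
  structure(list(vitc_tablet_mg = vitc_tablet_mg,
                 vitc_dilution_ml = vitc_dilution_ml,
                 stock_aliquot_ml = stock_aliquot_ml,
                 lugol_ml = lugol_ml,
                 water_ml = water_ml,
                 peroxide_ml = peroxide_ml),
            class = "clock_recipe")
}

#' Convert a recipe to initial molar concentrations
#'
#' The reaction volume is the sum of everything poured in
#' (water + stock aliquot + peroxide + Lugol's). The ascorbic-acid
#' concentration `c0` dilutes the stock aliquot into that volume; the
#' iodine-atom concentration `m0 = a0 + 2*b0` comes from the Lugol's
#' iodine content (2.5289 g per 100 ml, atomic mass 126.9 g/mol). How the
#' iodine atoms split between I2 (`b0`) and iodide (`a0`) is not known from
#' the recipe; that split, `phi = b0/m0`, is a fitting parameter.
#'
#' @param rec A [recipe()] object, or `lugol_ml` shorthand via `recipe()`.
#' @return A list with `c0` (mol/l), `m0` (mol I atoms / l) and
#'   `total_volume_ml`.
#' @examples
#' recipe_to_concentrations(recipe(vitc_dilution_ml = 60, lugol_ml = 5))
#' # c0 = 0.003263, m0 = 0.0068718 mol/l in a 145 ml volume
#' @export
recipe_to_concentrations <- function(rec) {
  if (!inherits(rec, "clock_recipe"))
    stop_validation("`rec` must be a clock_recipe object; see recipe()")
  total_ml <- rec$water_ml + rec$stock_aliquot_ml + rec$peroxide_ml + rec$lugol_ml
  stock <- vitc_stock_concentration(rec$vitc_tablet_mg, rec$vitc_dilution_ml)
  c0 <- stock * rec$stock_aliquot_ml / total_ml
  iodine_g <- rec$lugol_ml * lugol_iodine_content() / 100
  m0 <- (iodine_g / .stoich$M_I) / (total_ml / 1000)
  list(c0 = c0, m0 = m0, total_volume_ml = total_ml)
}
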