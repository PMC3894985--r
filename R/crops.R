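#' The crop vocabulary
#'
#' The fifteen crops that appear in San Joaquin Valley cotton rotation
#' records. The vocabulary is closed: any other crop name in an input file
#' is an error, never silently grouped.
#'
#' @return Character vector of the 15 crop names, alphabetical.
#' @export
crop_vocabulary <- function() {
  c("alfalfa", "barley", "carrots", "corn", "cotton", "garbanzo", "garlic",
    "lettuce", "melons", "onions", "potatoes", "safflower", "sugarbeets",
    "tomatoes", "wheat")
}

#' Convert lint yield from bales/acre to kg/ha
#'
#' Grower records report cotton lint yield in bales per acre; all analyses
#' in this package work in kg/ha. One US cotton bale is taken as 217.72 kg
#' of lint (480 lb) and one acre as 0.404686 ha.
#'
#' @param x Numeric vector of yields in bales/acre.
#' @param bale_kg Mass of one bale in kg.
#' @param acre_ha Area of one acre in hectares.
#' @return Numeric vector of yields in kg/ha.
#' @examples
#' bales_acre_to_kg_ha(2.5)
#' @export
bales_acre_to_kg_ha <- function(x, bale_kg = 217.72, acre_ha = 0.404686) {
  x * bale_kg / acre_ha
}
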