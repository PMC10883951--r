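#' Chemical name vocabulary
#'
#' A packaged vocabulary of chemical substance names with CAS registry
#' segments.  It serves two roles: the synthetic SDS generator samples
#' ingredients from it, and (minus a held-out slice) it is the default
#' gazetteer behind the ingredient-name recognizer.  Check digits are always
#' computed from the segments, never stored, so every vocabulary CAS passes
#' the checksum by construction.  The first block lists common industrial
#' chemicals with their real registry segments; the combinatorial block
#' carries synthetic salt-style names with synthetic (but checksum-valid)
#' registry numbers, clearly separated so nobody mistakes them for real
#' registry assignments.
#'
#' @name vocabulary
NULL

.sdsindex_env <- new.env(parent = emptyenv())

common_chemicals <- function() {
  # name | first segment | second segment (real registry segments)
  txt <- c(
    "water|7732|18", "acetone|67|64", "ethanol|64|17", "methanol|67|56",
    "toluene|108|88", "xylene|1330|20", "benzene|71|43",
    "titanium dioxide|13463|67", "sodium hydroxide|1310|73",
    "sulfuric acid|7664|93", "hydrochloric acid|7647|01",
    "ammonia|7664|41", "glycerol|56|81", "isopropanol|67|63",
    "ethylene glycol|107|21", "propylene glycol|57|55",
    "formaldehyde|50|00", "phenol|108|95", "styrene|100|42",
    "sodium chloride|7647|14", "calcium carbonate|471|34",
    "quartz|14808|60", "carbon black|1333|86", "zinc oxide|1314|13",
    "hydrogen peroxide|7722|84", "acetic acid|64|19",
    "citric acid|77|92", "sodium hypochlorite|7681|52",
    "potassium hydroxide|1310|58", "nitric acid|7697|37",
    "phosphoric acid|7664|38", "methyl ethyl ketone|78|93",
    "ethyl acetate|141|78", "butyl acetate|123|86", "hexane|110|54",
    "heptane|142|82", "cyclohexane|110|82", "dichloromethane|75|09",
    "chloroform|67|66", "carbon dioxide|124|38", "naphthalene|91|20",
    "limonene|5989|27", "ethylbenzene|100|41",
    "methyl methacrylate|80|62", "acrylic acid|79|10",
    "sodium carbonate|497|19", "magnesium oxide|1309|48",
    "calcium oxide|1305|78", "sodium sulfate|7757|82", "urea|57|13",
    "glycine|56|40", "benzoic acid|65|85", "salicylic acid|69|72",
    "oleic acid|112|80", "stearic acid|57|11", "lauric acid|143|07",
    "sodium lauryl sulfate|151|21", "aluminium oxide|1344|28",
    "iron oxide|1309|37", "talc|14807|96", "kaolin|1332|58",
    "paraffin wax|8002|74", "mineral oil|8042|47", "ethyl alcohol|64|17"
  )
  parts <- strsplit(txt, "|", fixed = TRUE)
  data.frame(
    name = vapply(parts, `[`, "", 1),
    seg1 = vapply(parts, `[`, "", 2),
    seg2 = vapply(parts, `[`, "", 3),
    synthetic = FALSE,
    stringsAsFactors = FALSE
  )
}

synthetic_chemicals <- function() {
  cations <- c("sodium", "potassium", "calcium", "magnesium", "ammonium",
               "zinc", "barium", "lithium", "copper", "strontium")
  anions <- c("benzoate", "citrate", "gluconate", "sulfonate", "stearate",
              "silicate", "borate", "laurate", "oleate", "tartrate",
              "salicylate", "propionate", "glutamate", "fumarate",
              "malonate", "succinate")
  grid <- expand.grid(cation = cations, anion = anions,
                      stringsAsFactors = FALSE)
  i <- seq_len(nrow(grid))
  data.frame(
    name = paste(grid$cation, grid$anion),
    # synthetic registry segments, deliberately in a high range
    seg1 = as.character(900000L + 37L * i),
    seg2 = sprintf("%02d", 10L + (i * 7L) %% 90L),
    synthetic = TRUE,
    stringsAsFactors = FALSE
  )
}

#' The packaged chemical vocabulary
#'
#' @param include_held_out keep the held-out slice (names excluded from the
#'   default gazetteer so recognizer misses can be measured)?
#' @return data.frame with columns `name`, `seg1`, `seg2`, `cas` (full
#'   checksum-valid CAS string), `synthetic`, `held_out`
#' @export
chemical_vocabulary <- function(include_held_out = TRUE) {
  if (is.null(.sdsindex_env$vocab)) {
    v <- rbind(common_chemicals(), synthetic_chemicals())
    stopifnot(!anyDuplicated(v$name))
    check <- vapply(paste0(v$seg1, v$seg2), cas_check_digit, integer(1))
    v$cas <- paste0(v$seg1, "-", v$seg2, "-", check)
    # every 10th entry is held out of the default gazetteer
    v$held_out <- (seq_len(nrow(v)) %% 10L) == 0L
    .sdsindex_env$vocab <- v
  }
  v <- .sdsindex_env$vocab
  if (!include_held_out) v[!v$held_out, , drop = FALSE] else v
}

#' Default gazetteer: vocabulary names minus the held-out slice
#' @return character vector of lowercase names
#' @export
default_gazetteer <- function() {
  chemical_vocabulary(include_held_out = FALSE)$name
}
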