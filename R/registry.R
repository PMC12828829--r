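# Lipid class registry and species-level shorthand grammar.
#
# Species are named at the species level: "CLASS [O-|P-]C:D[;On][ dK]", e.g.
# "PC 34:2", "Cer 38:1;O2", "PC P-36:1 d9", "Chol d7". Compositions are
# derived from a per-class backbone anchored on one reference species with a
# published structural formula, plus CH2 per acyl carbon and minus H2 per
# double bond. Ether (O-) linkage replaces one ester oxygen (-O +H2);
# plasmalogen (P-) is ether plus one double-bond equivalent (net -O).

#' Load the lipid class registry
#'
#' The registry maps each lipid class to its backbone composition (the class
#' formula at 0 acyl carbons and 0 double bonds), the per-carbon and
#' per-double-bond increments, the default oxygen annotation (sphingolipids
#' default to the `;O2` backbone), and the adduct observed in each ionization
#' polarity. It ships as editable tab-separated text under
#' `inst/extdata/lipid_classes.tsv`.
#'
#' @param path Optional path to an alternative registry file.
#' @return A tibble with one row per lipid class.
#' @export
lipid_registry <- function(path = NULL) {
  if (is.null(path) && !is.null(the$registry)) return(the$registry)
  file <- path %||% system.file("extdata", "lipid_classes.tsv", package = "lipidpipe")
  reg <- readr::read_tsv(file, col_types = readr::cols(.default = "c"), progress = FALSE)
  reg$default_oxygens <- as.integer(reg$default_oxygens)
  if (is.null(path)) the$registry <- reg
  reg
}

registry_row <- function(class, registry = lipid_registry()) {
  i <- match(class, registry$class)
  if (is.na(i)) {
    stop("lipid class '", class, "' is not in the registry", call. = FALSE)
  }
  registry[i, ]
}

# Table 1 mix names that do not follow the species-level grammar.
LIPID_ALIASES <- c(
  "Cer C18 d7" = "Cer 36:1;O2 d7",
  "Cer C18"    = "Cer 36:1;O2"
)

CLASS_ALIASES <- c(GlcCer = "HexCer")

SHORTHAND_RE <- paste0(
  "^([A-Za-z][A-Za-z0-9]*)",          # class code
  "(?:\\s+(O-|P-)?(\\d+):(\\d+)",     # optional linkage + C:D
  "(?:;O(\\d+))?)?",                  # optional oxygen annotation
  "(?:\\s+d(\\d+))?$"                 # optional deuterium label
)

#' Parse species-level lipid shorthand
#'
#' @param name A shorthand name such as `"PC 34:2"`, `"Cer 38:1;O2"`,
#'   `"PC P-36:1 d9"` or `"Chol d7"`. The nonstandard internal-standard mix
#'   names (`"Cer C18 d7"`, `"GlcCer 36:1 d5"`) are accepted via an alias
#'   table.
#' @param registry Lipid class registry, see [lipid_registry()].
#' @return A one-row tibble with columns `species` (canonical display name),
#'   `class`, `class_label` (class plus `" O-"` for ether/plasmalogen
#'   species), `carbons`, `db`, `oxygens`, `linkage` (`"ester"`, `"O-"` or
#'   `"P-"`), and `label_d` (deuterium count).
#' @export
parse_lipid <- function(name, registry = lipid_registry()) {
  stopifnot(is.character(name), length(name) == 1L)
  raw <- trimws(name)
  if (raw %in% names(LIPID_ALIASES)) raw <- LIPID_ALIASES[[raw]]
  m <- regmatches(raw, regexec(SHORTHAND_RE, raw))[[1]]
  if (length(m) == 0L) {
    stop("cannot parse lipid name '", name, "'", call. = FALSE)
  }
  class <- m[2]
  if (class %in% names(CLASS_ALIASES)) class <- CLASS_ALIASES[[class]]
  row <- tryCatch(registry_row(class, registry), error = function(e) {
    stop("cannot parse lipid name '", name, "': unknown class token '",
         m[2], "'", call. = FALSE)
  })
  has_cd <- nzchar(m[3]) || nzchar(m[4])
  linkage <- if (nzchar(m[3])) m[3] else "ester"
  carbons <- if (nzchar(m[4])) as.integer(m[4]) else 0L
  db <- if (nzchar(m[5])) as.integer(m[5]) else 0L
  oxygens <- if (nzchar(m[6])) as.integer(m[6]) else row$default_oxygens
  label_d <- if (nzchar(m[7])) as.integer(m[7]) else 0L
  if (!has_cd && !class %in% c("Chol")) {
    stop("cannot parse lipid name '", name,
         "': missing carbons:double-bonds token", call. = FALSE)
  }
  sp <- tibble::tibble(
    class = class, class_label = class_label(class, linkage),
    carbons = carbons, db = db, oxygens = oxygens,
    linkage = linkage, label_d = label_d
  )
  sp$species <- format_lipid(sp)
  sp[, c("species", "class", "class_label", "carbons", "db", "oxygens",
         "linkage", "label_d")]
}

#' Parse a vector of shorthand names
#'
#' @param names Character vector of shorthand names.
#' @inheritParams parse_lipid
#' @return A tibble with one row per name (see [parse_lipid()]).
#' @export
parse_lipids <- function(names, registry = lipid_registry()) {
  dplyr::bind_rows(lapply(names, parse_lipid, registry = registry))
}

#' Format a parsed species back to canonical shorthand
#'
#' `parse_lipid(format_lipid(x))` is the identity; default oxygen
#' annotations (the sphingolipid `;O2`) are always printed explicitly.
#'
#' @param species A one- or multi-row tibble as returned by [parse_lipid()].
#' @param registry Lipid class registry.
#' @return Character vector of canonical names.
#' @export
format_lipid <- function(species, registry = lipid_registry()) {
  vapply(seq_len(nrow(species)), function(i) {
    s <- species[i, ]
    row <- registry_row(s$class, registry)
    cd <- if (s$class == "Chol" && s$carbons == 0L) "" else {
      paste0(" ", if (s$linkage == "ester") "" else s$linkage,
             s$carbons, ":", s$db,
             if (s$oxygens > 0L) paste0(";O", s$oxygens) else "")
    }
    lab <- if (s$label_d > 0L) paste0(" d", s$label_d) else ""
    paste0(s$class, cd, lab)
  }, character(1))
}

#' Class label grouping ether and plasmalogen species
#'
#' Ether and plasmalogen species of a class are summarized together (the
#' `"PC O-"` convention); ester species keep the bare class code.
#'
#' @param class Class code(s).
#' @param linkage `"ester"`, `"O-"` or `"P-"`.
#' @return Character vector of class labels.
#' @export
class_label <- function(class, linkage) {
  ifelse(linkage %in% c("O-", "P-"), paste(class, "O-"), class)
}

#' Elemental composition of a lipid species
#'
#' Backbone + carbons x CH2 - double_bonds x H2, adjusted for ether or
#' plasmalogen linkage, extra oxygen annotation beyond the class default, and
#' the deuterium label (which substitutes H for D, leaving the total
#' hydrogen count unchanged).
#'
#' @param species Shorthand name or a parsed species tibble row.
#' @param registry Lipid class registry.
#' @return Named integer vector of element counts.
#' @export
lipid_composition <- function(species, registry = lipid_registry()) {
  if (is.character(species)) species <- parse_lipid(species, registry)
  s <- species[1, ]
  row <- registry_row(s$class, registry)
  comp <- comp_canon(parse_formula(row$backbone))
  comp <- comp_add(comp, parse_formula(row$carbon_increment), scale = s$carbons)
  comp <- comp_add(comp, parse_formula(row$double_bond_decrement), scale = -s$db)
  if (s$linkage %in% c("O-", "P-")) {
    comp <- comp_add(comp, c(O = -1L, H = 2L))          # ester -> ether
    if (s$linkage == "P-") comp <- comp_add(comp, c(H = -2L))  # vinyl ether
  }
  extra_o <- s$oxygens - row$default_oxygens
  if (extra_o != 0L) comp <- comp_add(comp, c(O = as.integer(extra_o)))
  if (s$label_d > 0L) {
    comp <- comp_add(comp, c(H = -s$label_d, D = s$label_d))
  }
  if (comp[["C"]] < 1L) {
    stop("species '", s$species, "' yields no carbon atoms", call. = FALSE)
  }
  comp_check(comp, paste0("composition of '", s$species, "'"))
}

#' Adduct for a class in a given polarity
#'
#' Encodes the observed ionization behavior: most classes protonate in
#' positive mode, PI is ammoniated, Cer loses water from the protonated ion;
#' in negative mode LPE/PE/PG/PI/PS deprotonate while Cer/HexCer/LPC/PC/SM
#' form acetate adducts. Returns `NA` when the class is not observed in the
#' requested polarity.
#'
#' @param class Class code(s).
#' @param polarity `"positive"` or `"negative"`.
#' @param registry Lipid class registry.
#' @return Character vector of adduct names (`NA` where unavailable).
#' @export
class_adduct <- function(class, polarity = c("positive", "negative"),
                         registry = lipid_registry()) {
  polarity <- match.arg(polarity)
  col <- if (polarity == "positive") "positive_adduct" else "negative_adduct"
  out <- vapply(class, function(cl) registry_row(cl, registry)[[col]], character(1))
  out[out == "none"] <- NA_character_
  unname(out)
}

#' Theoretical m/z of a lipid species under a class adduct
#'
#' @param species Shorthand name or parsed species row.
#' @param polarity `"positive"` or `"negative"`; the class's registered
#'   adduct for that polarity is used.
#' @param adduct Optional explicit adduct name overriding the registry; it
#'   must still be one the registry allows for the class.
#' @param registry Lipid class registry.
#' @return m/z in Da.
#' @export
lipid_mz <- function(species, polarity = c("positive", "negative"),
                     adduct = NULL, registry = lipid_registry()) {
  polarity <- match.arg(polarity)
  if (is.character(species)) species <- parse_lipid(species, registry)
  cls_add <- class_adduct(species$class[1], polarity, registry)
  if (is.null(adduct)) adduct <- cls_add
  if (is.na(adduct) || !identical(adduct, cls_add)) {
    stop("class ", species$class[1], " has no adduct '",
         if (is.null(adduct) || is.na(adduct)) "<none>" else adduct,
         "' registered in ", polarity, " mode", call. = FALSE)
  }
  adduct_mz(lipid_composition(species, registry), adduct)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
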