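# SBML Level 3 Version 1 export/import of an enumerated CRN.
#
# One compartment of unit volume; concentrations in nM, time in seconds;
# mass-action kinetic laws k * [r1] (* [r2]). Reaction descriptors (kind,
# effective toehold length, context flags) travel in an annotation element so
# the canonical reaction table round-trips exactly.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
DSD_NS <- "https://dsdfibril.r-lib.org/ns"

sanitize_id <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[A-Za-z_]", x), x, paste0("s_", x))
}

#' Export a CRN to SBML (Level 3 Version 1)
#'
#' @param crn A `dsd_crn`.
#' @param path Output path; `NULL` returns the `xml_document`.
#' @param init Optional named initial concentrations (nM) by species label.
#' @return The path (invisibly) or the document.
#' @export
write_sbml <- function(crn, path = NULL, init = NULL) {
  stopifnot(inherits(crn, "dsd_crn"))
  sp <- crn$species_tbl
  ids <- sanitize_id(sp$label)
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  id_of <- stats::setNames(ids, sp$key)
  x0 <- stats::setNames(numeric(nrow(sp)), sp$label)
  if (!is.null(init)) x0[names(init)] <- init

  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = "dsd_crn",
                               timeUnits = "second", extentUnits = "nanomole")
  uds <- xml2::xml_add_child(model, "listOfUnitDefinitions")
  add_unit <- function(id, kinds) {
    ud <- xml2::xml_add_child(uds, "unitDefinition", id = id)
    lo <- xml2::xml_add_child(ud, "listOfUnits")
    for (k in kinds) {
      xml2::xml_add_child(lo, "unit", kind = k$kind,
                          exponent = as.character(k$exp),
                          scale = as.character(k$scale), multiplier = "1")
    }
  }
  add_unit("nanomolar", list(list(kind = "mole", exp = 1, scale = -9),
                             list(kind = "litre", exp = -1, scale = 0)))
  add_unit("per_second", list(list(kind = "second", exp = -1, scale = 0)))
  add_unit("per_nanomolar_per_second",
           list(list(kind = "mole", exp = -1, scale = -9),
                list(kind = "litre", exp = 1, scale = 0),
                list(kind = "second", exp = -1, scale = 0)))
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "cell", size = "1",
                      spatialDimensions = "3", constant = "true")
  ls <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(sp))) {
    xml2::xml_add_child(ls, "species", id = ids[i], name = sp$label[i],
                        compartment = "cell",
                        initialConcentration = format(x0[[sp$label[i]]], digits = 17),
                        substanceUnits = "nanomole",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  rx <- crn$reactions
  lr <- xml2::xml_add_child(model, "listOfReactions")
  for (j in seq_len(nrow(rx))) {
    r <- xml2::xml_add_child(lr, "reaction", id = sprintf("r%04d", j),
                             reversible = "false")
    ann <- xml2::xml_add_child(r, "annotation")
    xml2::xml_add_child(ann, "descriptor", xmlns = DSD_NS,
                        kind = rx$kind[j],
                        n_eff = as.character(rx$n_eff[j]),
                        loop = as.character(rx$loop[j]),
                        teth = as.character(rx$teth[j]),
                        mult = as.character(rx$mult[j]))
    rl <- xml2::xml_add_child(r, "listOfReactants")
    rkeys <- c(rx$r1[j], rx$r2[j]); rkeys <- rkeys[!is.na(rkeys)]
    for (k in unique(rkeys)) {
      xml2::xml_add_child(rl, "speciesReference", species = id_of[[k]],
                          stoichiometry = as.character(sum(rkeys == k)),
                          constant = "true")
    }
    pkeys <- c(rx$p1[j], rx$p2[j], rx$p3[j]); pkeys <- pkeys[!is.na(pkeys)]
    pl <- xml2::xml_add_child(r, "listOfProducts")
    for (k in unique(pkeys)) {
      xml2::xml_add_child(pl, "speciesReference", species = id_of[[k]],
                          stoichiometry = as.character(sum(pkeys == k)),
                          constant = "true")
    }
    kl <- xml2::xml_add_child(r, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    xml2::xml_add_child(ap, "ci", "k")
    for (k in rkeys) xml2::xml_add_child(ap, "ci", id_of[[k]])
    lp <- xml2::xml_add_child(kl, "listOfLocalParameters")
    xml2::xml_add_child(lp, "localParameter", id = "k",
                        value = format(rx$rate[j], digits = 17),
                        units = if (length(rkeys) == 2L)
                          "per_nanomolar_per_second" else "per_second")
  }
  if (is.null(path)) return(doc)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a CRN from SBML
#'
#' Reads a document written by [write_sbml()] back into species and reaction
#' tables; the canonical reaction table (kinds, descriptors, rates) is
#' preserved exactly.
#'
#' @param path SBML file.
#' @return List of class `dsd_crn_tables`: `species` (tibble `id`, `label`,
#'   `init_nM`) and `reactions` (tibble as in a `dsd_crn`, with labels in the
#'   reactant/product columns).
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, m = "http://www.w3.org/1998/Math/MathML", d = DSD_NS)
  spn <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  species <- tibble::tibble(
    id = xml2::xml_attr(spn, "id"),
    label = xml2::xml_attr(spn, "name"),
    init_nM = as.numeric(xml2::xml_attr(spn, "initialConcentration"))
  )
  lab_of <- stats::setNames(species$label, species$id)
  rxn <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  parse_side <- function(node, xp) {
    refs <- xml2::xml_find_all(node, xp, ns)
    ids <- xml2::xml_attr(refs, "species")
    st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    rep(unname(lab_of[ids]), times = st)
  }
  rows <- lapply(rxn, function(r) {
    desc <- xml2::xml_find_first(r, ".//d:descriptor", ns)
    rs <- parse_side(r, ".//s:listOfReactants/s:speciesReference")
    ps <- parse_side(r, ".//s:listOfProducts/s:speciesReference")
    kv <- xml2::xml_find_first(r, ".//s:localParameter[@id='k']", ns)
    ne <- xml2::xml_attr(desc, "n_eff")
    lp <- xml2::xml_attr(desc, "loop")
    tibble::tibble(
      kind = xml2::xml_attr(desc, "kind"),
      r1 = rs[1L], r2 = if (length(rs) > 1L) rs[2L] else NA_character_,
      p1 = ps[1L], p2 = if (length(ps) > 1L) ps[2L] else NA_character_,
      p3 = if (length(ps) > 2L) ps[3L] else NA_character_,
      n_eff = ifelse(ne == "NA", NA_integer_, as.integer(ne)),
      loop = ifelse(lp == "NA", NA, as.logical(lp)),
      teth = {
        tt <- xml2::xml_attr(desc, "teth")
        ifelse(tt == "NA", NA_integer_, as.integer(tt))
      },
      mult = as.integer(xml2::xml_attr(desc, "mult")),
      rate = as.numeric(xml2::xml_attr(kv, "value"))
    )
  })
  reactions <- dplyr::bind_rows(rows)
  structure(list(species = species, reactions = reactions),
            class = "dsd_crn_tables")
}
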