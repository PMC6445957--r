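#' Load a signaling model description
#'
#' Reads a model from the native structured (YAML) format or from SBML Level 3
#' (dispatch on file extension, falling back to content sniffing). The loaded
#' roster is validated: rate-law kinds are restricted to `hill_activation`,
#' `hill_repression` and `mass_action`, and unknown laws are rejected loudly
#' rather than silently misparsed.
#'
#' @param path File path (`.yaml`/`.yml` native, `.xml`/`.sbml` SBML).
#' @return A validated [ec_model()].
#' @examples
#' f <- system.file("extdata", "ec_model.yaml", package = "angiosprout")
#' m <- load_model(f)
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) return(read_model_yaml(path))
  if (ext %in% c("xml", "sbml")) return(read_sbml(path))
  head <- readChar(path, nchars = 64, useBytes = TRUE)
  if (grepl("^\\s*<\\?xml|^\\s*<sbml", head)) read_sbml(path)
  else read_model_yaml(path)
}

#' Write a signaling model description
#'
#' @param model An [ec_model()].
#' @param path Destination; `.yaml`/`.yml` writes the native format,
#'   `.xml`/`.sbml` writes SBML Level 3.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  validate_model(model)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xml", "sbml")) write_sbml(model, path)
  else write_model_yaml(model, path)
  invisible(path)
}

# ---- native YAML format ----------------------------------------------------

write_model_yaml <- function(model, path) {
  rx <- lapply(model$reactions, function(r) {
    out <- list(name = r$name, law = r$law, params = as.list(r$params))
    if (r$law == "mass_action") {
      out$rate_species <- as.list(r$rate_species)
    } else {
      out$modifiers <- lapply(r$modifiers, as.list)
    }
    out$stoich <- as.list(r$stoich)
    out
  })
  yaml::write_yaml(list(
    format = "angiosprout-model",
    version = model$format_version,
    species = as.list(model$species),
    env_species = as.list(model$env_species),
    rule_species = as.list(model$rule_species),
    parameters = as.list(model$params),
    initial = as.list(model$initial),
    reactions = rx
  ), path, precision = 15L)
}

read_model_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$format) || y$format != "angiosprout-model") {
    stop("not an angiosprout model description: ", path, call. = FALSE)
  }
  if (length(y$species) == 0) stop("model declares no species", call. = FALSE)
  rx <- lapply(y$reactions, function(r) {
    out <- list(name = r$name, law = r$law,
                params = unlist(r$params))
    if (identical(r$law, "mass_action")) {
      out$rate_species <- unlist(r$rate_species)
    } else {
      out$modifiers <- lapply(r$modifiers, unlist)
    }
    out$stoich <- unlist(r$stoich)
    out
  })
  m <- structure(list(
    species = unlist(y$species),
    env_species = unlist(y$env_species),
    rule_species = unlist(y$rule_species),
    params = unlist(y$parameters),
    initial = unlist(y$initial),
    reactions = rx,
    format_version = as.integer(y$version)
  ), class = "ec_model")
  validate_model(m)
}

# ---- SBML Level 3 ----------------------------------------------------------

ANGIO_NS <- "urn:angiosprout:model"

mml <- list(
  ci = function(x) paste0("<ci> ", x, " </ci>"),
  cn = function(x) paste0("<cn> ", format(x, digits = 15), " </cn>"),
  ap = function(op, ...) paste0("<apply><", op, "/>",
                                paste0(..., collapse = ""), "</apply>")
)

mml_sum <- function(ids) {
  if (length(ids) == 1) mml$ci(ids) else do.call(mml$ap, c("plus",
                                                           lapply(ids, mml$ci)))
}

mml_hill_factor <- function(mod_ids, a, m0, h, repressing) {
  mod <- mml_sum(mod_ids)
  num <- if (repressing) mml$ap("power", mml$ci(m0), mml$ci(h))
         else mml$ap("power", mod, mml$ci(h))
  frac <- mml$ap("divide", num,
                 mml$ap("plus", mml$ap("power", mod, mml$ci(h)),
                        mml$ap("power", mml$ci(m0), mml$ci(h))))
  mml$ap("plus",
         mml$ap("divide", mml$cn(1), mml$ci(a)),
         mml$ap("times",
                mml$ap("minus", mml$cn(1),
                       mml$ap("divide", mml$cn(1), mml$ci(a))),
                frac))
}

reaction_mathml <- function(r) {
  body <- if (r$law == "mass_action") {
    do.call(mml$ap, c("times", lapply(c(r$params[["k"]], r$rate_species),
                                      mml$ci)))
  } else {
    parts <- list(mml$ci(r$params[["vmax"]]),
                  mml_hill_factor(r$modifiers$mod, r$params[["a"]],
                                  r$params[["m0"]], r$params[["h"]],
                                  r$law == "hill_repression"))
    if (!is.null(r$modifiers$mod2)) {
      parts <- c(parts, list(mml_hill_factor(r$modifiers$mod2,
                                             r$params[["a2"]],
                                             r$params[["m02"]],
                                             r$params[["h"]], FALSE)))
    }
    do.call(mml$ap, c("times", parts))
  }
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">', body, "</math>")
}

write_sbml <- function(model, path) {
  sp <- vapply(model$species, function(s) {
    x0 <- if (s %in% names(model$initial)) model$initial[[s]] else 0
    boundary <- tolower(s %in% model$env_species)
    sprintf(paste0('<species id="%s" compartment="cell" initialAmount="%s" ',
                   'hasOnlySubstanceUnits="true" boundaryCondition="%s" ',
                   'constant="false"/>'),
            s, format(x0, digits = 15), boundary)
  }, "")
  pars <- vapply(names(model$params), function(p) {
    sprintf('<parameter id="%s" value="%s" constant="true"/>', p,
            format(model$params[[p]], digits = 15))
  }, "")
  rxs <- vapply(model$reactions, function(r) {
    st <- r$stoich
    reac <- names(st)[st < 0]
    prod <- names(st)[st > 0]
    side <- function(tag, sps, coefs) {
      if (!length(sps)) return("")
      paste0("<listOf", tag, "s>",
             paste0(sprintf(paste0('<speciesReference species="%s" ',
                                   'stoichiometry="%s" constant="true"/>'),
                            sps, format(abs(coefs), digits = 15)),
                    collapse = ""),
             "</listOf", tag, "s>")
    }
    mods <- if (r$law == "mass_action") setdiff(r$rate_species, reac)
            else unique(unlist(r$modifiers))
    modxml <- if (length(mods)) {
      paste0("<listOfModifiers>",
             paste0(sprintf('<modifierSpeciesReference species="%s"/>', mods),
                    collapse = ""), "</listOfModifiers>")
    } else ""
    ann <- paste0('<annotation><angio:rateLaw xmlns:angio="', ANGIO_NS,
                  '" law="', r$law, '" ',
                  paste0(names(r$params), '="', r$params, '"',
                         collapse = " "),
                  if (r$law == "mass_action") {
                    paste0(' rateSpecies="',
                           paste(r$rate_species, collapse = " "), '"')
                  } else {
                    paste0(' mod="', paste(r$modifiers$mod, collapse = " "),
                           '"',
                           if (!is.null(r$modifiers$mod2)) {
                             paste0(' mod2="',
                                    paste(r$modifiers$mod2, collapse = " "),
                                    '"')
                           } else "")
                  },
                  "/></annotation>")
    sprintf(paste0('<reaction id="%s" reversible="false">%s%s%s%s',
                   "<kineticLaw>%s</kineticLaw></reaction>"),
            r$name, ann, side("Reactant", reac, st[st < 0]),
            side("Product", prod, st[st > 0]), modxml, reaction_mathml(r))
  }, "")
  roster_ann <- paste0('<annotation><angio:roster xmlns:angio="', ANGIO_NS,
                       '" env="', paste(model$env_species, collapse = " "),
                       '" rule="', paste(model$rule_species, collapse = " "),
                       '" version="', model$format_version,
                       '"/></annotation>')
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
    'level="3" version="2">',
    '<model id="ec_intracellular_signaling" ',
    'substanceUnits="item" timeUnits="hour">',
    roster_ann,
    '<listOfCompartments><compartment id="cell" constant="true" ',
    'spatialDimensions="3" size="1"/></listOfCompartments>',
    "<listOfSpecies>", paste0(sp, collapse = ""), "</listOfSpecies>",
    "<listOfParameters>", paste0(pars, collapse = ""), "</listOfParameters>",
    "<listOfReactions>", paste0(rxs, collapse = ""), "</listOfReactions>",
    "</model></sbml>")
  # parse/serialize through xml2 so the output is well-formed, indented XML
  xml2::write_xml(xml2::read_xml(doc), path)
  invisible(path)
}

read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core", a = ANGIO_NS)
  roster <- xml2::xml_find_first(doc, ".//a:roster", ns)
  if (inherits(roster, "xml_missing")) {
    stop("SBML file lacks the roster annotation; cannot identify ",
         "environment/rule species", call. = FALSE)
  }
  splitws <- function(x) if (is.na(x) || x == "") character(0)
                         else strsplit(x, " ", fixed = TRUE)[[1]]
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  species <- xml2::xml_attr(sp_nodes, "id")
  x0 <- as.numeric(xml2::xml_attr(sp_nodes, "initialAmount"))
  env_species <- splitws(xml2::xml_attr(roster, "env"))
  rule_species <- splitws(xml2::xml_attr(roster, "rule"))
  par_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter",
                                  ns)
  params <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                            xml2::xml_attr(par_nodes, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rx <- lapply(rx_nodes, function(node) {
    name <- xml2::xml_attr(node, "id")
    ann <- xml2::xml_find_first(node, ".//a:rateLaw", ns)
    if (inherits(ann, "xml_missing")) {
      stop("reaction '", name, "': no recognizable rate-law annotation",
           call. = FALSE)
    }
    law <- xml2::xml_attr(ann, "law")
    if (!law %in% c("hill_activation", "hill_repression", "mass_action")) {
      stop("reaction '", name, "': unknown rate law '", law, "'",
           call. = FALSE)
    }
    reac <- xml2::xml_find_all(node, ".//s:listOfReactants/s:speciesReference",
                               ns)
    prod <- xml2::xml_find_all(node, ".//s:listOfProducts/s:speciesReference",
                               ns)
    st <- c(stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                            xml2::xml_attr(reac, "species")),
            stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                            xml2::xml_attr(prod, "species")))
    out <- list(name = name, law = law)
    if (law == "mass_action") {
      out$params <- c(k = xml2::xml_attr(ann, "k"))
      out$rate_species <- splitws(xml2::xml_attr(ann, "rateSpecies"))
    } else {
      out$params <- c(vmax = xml2::xml_attr(ann, "vmax"),
                      a = xml2::xml_attr(ann, "a"),
                      m0 = xml2::xml_attr(ann, "m0"),
                      h = xml2::xml_attr(ann, "h"))
      out$modifiers <- list(mod = splitws(xml2::xml_attr(ann, "mod")))
      mod2 <- splitws(xml2::xml_attr(ann, "mod2"))
      if (length(mod2)) {
        out$params <- c(out$params, a2 = xml2::xml_attr(ann, "a2"),
                        m02 = xml2::xml_attr(ann, "m02"))
        out$modifiers$mod2 <- mod2
      }
    }
    out$stoich <- st
    out
  })
  initial <- stats::setNames(x0, species)
  initial <- initial[setdiff(species, env_species)]
  version <- suppressWarnings(as.integer(xml2::xml_attr(roster, "version")))
  m <- structure(list(
    species = species, env_species = env_species,
    rule_species = rule_species, params = params, initial = initial,
    reactions = rx,
    format_version = if (is.na(version)) 1L else version
  ), class = "ec_model")
  validate_model(m)
}
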