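# Readers and writers: the tab-separated reaction-table format, a minimal
# SBML Level 3 importer, and JSON-lines (de)serialization of metabolisms.
#
# Reaction-table layout (diff-able, bit-exact round trips):
#   # SynFBA-universe v1
#   # biomass: R_biomass
#   # medium: m1,m2          (line omitted when empty)
#   # extracellular: C1_ext,C2_ext
#   reaction_id <TAB> equation <TAB> flags
# Equations use "=>" / "<=>" arrows and "+"-separated terms with optional
# integer/real coefficients ("2 A + B => C"); an empty side is allowed
# (biomass sink). Flags: comma-separated subset of {transport, biomass},
# or "-".

.formatEquation <- function(stoich, reversible) {
  bad <- grepl("[[:space:]+]", names(stoich))
  if (any(bad))
    stop("metabolite ids with whitespace or '+' cannot be serialized: ",
         paste(names(stoich)[bad], collapse = ", "))
  side <- function(v) {
    if (!length(v)) return("")
    paste(ifelse(abs(v) == 1, names(v),
                 paste(format(abs(v), trim = TRUE), names(v))),
          collapse = " + ")
  }
  paste(side(stoich[stoich < 0]), if (reversible) "<=>" else "=>",
        side(stoich[stoich > 0]))
}

.parseEquation <- function(eq, id) {
  rev <- grepl("<=>", eq, fixed = TRUE)
  parts <- strsplit(eq, if (rev) "<=>" else "=>", fixed = TRUE)[[1]]
  if (length(parts) > 2 || !grepl("=>", eq, fixed = TRUE))
    stop("cannot parse equation of '", id, "': ", eq)
  parts <- c(parts, "")[1:2]
  term <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric())
    toks <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tk in toks) {
      bits <- strsplit(tk, "[[:space:]]+")[[1]]
      if (length(bits) == 1) out[bits] <- sign
      else if (length(bits) == 2) {
        co <- suppressWarnings(as.numeric(bits[1]))
        if (is.na(co)) stop("bad coefficient in '", id, "': ", tk)
        out[bits[2]] <- sign * co
      } else stop("bad term in '", id, "': ", tk)
    }
    out
  }
  s <- c(term(parts[1], -1), term(parts[2], 1))
  if (!length(s)) stop("empty stoichiometry in '", id, "'")
  list(stoich = s, reversible = rev)
}

#' Write a reaction universe as a tab-separated reaction table
#'
#' @param universe a [ReactionUniverse-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeUniverse <- function(universe, path) {
  S <- stoichiometry(universe)
  ids <- colnames(S)
  head <- c("# SynFBA-universe v1",
            paste0("# biomass: ", biomassId(universe)),
            if (length(universeMedium(universe)))
              paste0("# medium: ", paste(universeMedium(universe),
                                         collapse = ",")),
            paste0("# extracellular: ",
                   paste(names(which(isExtracellular(universe))),
                         collapse = ",")),
            "reaction_id\tequation\tflags")
  body <- vapply(ids, function(r) {
    s <- S[, r]; s <- s[s != 0]
    flags <- c(if (isTransport(universe)[r]) "transport",
               if (r == biomassId(universe)) "biomass")
    paste(r, .formatEquation(s, isReversible(universe)[r]),
          if (length(flags)) paste(flags, collapse = ",") else "-",
          sep = "\t")
  }, character(1))
  writeLines(c(head, body), path)
  invisible(path)
}

#' Read a reaction universe
#'
#' `format = "tsv"` reads the package's reaction-table format (see
#' [writeUniverse()]); `format = "sbml"` reads a user-supplied SBML Level 3
#' file via [readSBML()].
#'
#' @param path input file.
#' @param format `"tsv"` or `"sbml"`.
#' @param ... passed on to [readSBML()].
#' @return A [ReactionUniverse-class].
#' @export
readUniverse <- function(path, format = c("tsv", "sbml"), ...) {
  format <- match.arg(format)
  if (format == "sbml") return(readSBML(path, ...))
  lines <- readLines(path)
  grab <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), lines, value = TRUE)
    if (!length(ln)) return(character())
    strsplit(sub(paste0("^# ", key, ": "), "", ln[1]), ",", fixed = TRUE)[[1]]
  }
  biomass <- grab("biomass")
  extIds <- grab("extracellular")
  medium <- grab("medium")
  rows <- lines[!grepl("^#", lines) & nzchar(lines)]
  rows <- rows[-1]  # header
  fields <- strsplit(rows, "\t", fixed = TRUE)
  if (any(lengths(fields) != 3)) stop("malformed reaction table: ", path)
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicated reaction ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  parsed <- lapply(seq_along(ids), function(i)
    .parseEquation(fields[[i]][2], ids[i]))
  flags <- strsplit(vapply(fields, `[[`, character(1), 3), ",", fixed = TRUE)
  if (!length(biomass)) {
    biomass <- ids[vapply(flags, function(f) "biomass" %in% f, logical(1))]
    if (length(biomass) != 1) stop("no unique biomass reaction in ", path)
  }
  mids <- unique(unlist(lapply(parsed, function(p) names(p$stoich))))
  trip <- do.call(rbind, lapply(seq_along(ids), function(j) {
    s <- parsed[[j]]$stoich
    cbind(match(names(s), mids), j, s)
  }))
  S <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                            dims = c(length(mids), length(ids)),
                            dimnames = list(mids, ids))
  ReactionUniverse(S,
                   reversible = vapply(parsed, `[[`, logical(1), "reversible"),
                   transport = vapply(flags, function(f)
                     "transport" %in% f, logical(1)),
                   biomassId = biomass,
                   extracellular = mids %in% extIds,
                   medium = medium)
}

#' Minimal SBML Level 3 importer
#'
#' Reads species (id, compartment), reactions (reactants/products with
#' stoichiometries, `reversible` attribute) from an SBML document.
#' Compartments named/ids `e`, `ext` or `extracellular` mark extracellular
#' species; reactions touching both compartmental sides are flagged as
#' transport.
#'
#' @param path SBML file.
#' @param biomassId biomass reaction id; by default the first reaction id
#'   matching `biomass` (case-insensitive).
#' @param extracellularCompartments compartment ids treated as
#'   extracellular.
#' @return A [ReactionUniverse-class].
#' @export
readSBML <- function(path, biomassId = NULL,
                     extracellularCompartments = c("e", "ext",
                                                   "extracellular")) {
  doc <- xml2::read_xml(path)
  sp <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  mids <- xml2::xml_attr(sp, "id")
  comp <- xml2::xml_attr(sp, "compartment")
  ext <- setNames(comp %in% extracellularCompartments, mids)
  rxn <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  ids <- xml2::xml_attr(rxn, "id")
  if (anyDuplicated(ids)) stop("duplicated reaction ids in ", path)
  rev <- xml2::xml_attr(rxn, "reversible") %in% c("true", "1")
  stoichOf <- function(node) {
    ref <- function(xp, sign) {
      refs <- xml2::xml_find_all(node, xp)
      if (!length(refs)) return(numeric())
      co <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      co[is.na(co)] <- 1
      setNames(sign * co, xml2::xml_attr(refs, "species"))
    }
    c(ref(".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']", -1),
      ref(".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']", 1))
  }
  parsed <- lapply(rxn, stoichOf)
  if (is.null(biomassId)) {
    hit <- grep("biomass", ids, ignore.case = TRUE, value = TRUE)
    if (length(hit) < 1) stop("no biomass reaction found; pass biomassId")
    biomassId <- hit[1]
  }
  trip <- do.call(rbind, lapply(seq_along(ids), function(j) {
    s <- parsed[[j]]
    if (!length(s)) stop("reaction '", ids[j], "' has no stoichiometry")
    cbind(match(names(s), mids), j, s)
  }))
  S <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                            dims = c(length(mids), length(ids)),
                            dimnames = list(mids, ids))
  transport <- vapply(parsed, function(s) {
    e <- ext[names(s)]
    any(e) && !all(e)
  }, logical(1))
  ReactionUniverse(S, reversible = rev, transport = transport,
                   biomassId = biomassId, extracellular = ext,
                   medium = character())
}

#' Serialize / deserialize metabolism populations as JSON-lines
#'
#' One JSON object per line: `{"label": ..., "primary": ...,
#' "reactions": [...]}`.
#'
#' @param population list of [Metabolism-class] objects.
#' @param path file path.
#' @return `writePopulation` returns `path` invisibly; `readPopulation` a
#'   named list of [Metabolism-class] objects.
#' @export
writePopulation <- function(population, path) {
  lines <- vapply(population, function(m)
    jsonlite::toJSON(list(label = metabolismLabel(m),
                          primary = primaryCarbonSource(m),
                          reactions = reactionIds(m)),
                     auto_unbox = TRUE), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writePopulation
#' @param universe optional [ReactionUniverse-class] for membership checks.
#' @export
readPopulation <- function(path, universe = NULL) {
  lines <- readLines(path)
  pop <- lapply(lines, function(ln) {
    o <- jsonlite::fromJSON(ln)
    Metabolism(o$reactions, o$primary, label = o$label, universe = universe)
  })
  names(pop) <- vapply(pop, metabolismLabel, character(1))
  pop
}
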