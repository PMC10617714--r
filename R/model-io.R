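## Native toy-model JSON format ------------------------------------------
##
## {
##   "metabolites": [...],
##   "reactions":  [{"id","lb","ub","stoich":{met:coef}}, ...],
##   "enzymes":    [{"id","mw","kcats":{rxn:kcat_per_h}, "ub"}, ...],
##   "pool_total": number | null,
##   "biomass":    "reaction id"
## }

#' Read / write the native toy-model JSON format
#'
#' A compact JSON serialization of an [EnzymeConstrainedModel-class] used
#' for small test models and by the synthetic generator.  kcat values are
#' stored in h\eqn{^{-1}}.  The round trip `writeToyModel()` then
#' [readToyModel()] is lossless.
#'
#' @param path file path.
#' @return [readToyModel()] returns an [EnzymeConstrainedModel-class];
#'   `writeToyModel()` returns `path` invisibly.
#' @export
readToyModel <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- vapply(x$metabolites, identity, "")
  rid <- vapply(x$reactions, function(r) r$id, "")
  lb <- vapply(x$reactions, function(r) as.numeric(r$lb), 0)
  ub <- vapply(x$reactions, function(r) as.numeric(r$ub), 0)
  S <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(length(mets), length(rid)),
                            dimnames = list(mets, rid))
  for (k in seq_along(x$reactions)) {
    st <- x$reactions[[k]]$stoich
    if (length(st))
      S[match(names(st), mets), k] <- vapply(st, as.numeric, 0)
  }
  enz <- vapply(x$enzymes, function(e) e$id, "")
  mw <- vapply(x$enzymes, function(e)
    if (is.null(e$mw)) NA_real_ else as.numeric(e$mw), 0)
  eub <- vapply(x$enzymes, function(e)
    if (is.null(e$ub)) Inf else as.numeric(e$ub), 0)
  kc <- do.call(rbind, lapply(x$enzymes, function(e) {
    if (!length(e$kcats)) return(NULL)
    data.frame(enzyme = e$id, reaction = names(e$kcats),
               kcat = vapply(e$kcats, as.numeric, 0),
               stringsAsFactors = FALSE)
  }))
  EnzymeConstrainedModel(
    metabolites = mets, reactions = rid, S = S, lb = lb, ub = ub,
    biomassRxn = x$biomass, enzymes = enz, kcat = kc,
    poolTotal = if (is.null(x$pool_total)) NA_real_
                else as.numeric(x$pool_total),
    enzymeMw = stats::setNames(mw, enz),
    enzymeUb = stats::setNames(eub, enz))
}

#' @rdname readToyModel
#' @param model an [EnzymeConstrainedModel-class].
#' @export
writeToyModel <- function(model, path) {
  S <- model@S
  reactions <- lapply(seq_along(model@reactions), function(j) {
    nz <- which(S[, j] != 0)
    list(id = model@reactions[j], lb = model@lb[j], ub = model@ub[j],
         stoich = as.list(stats::setNames(as.numeric(S[nz, j]),
                                          model@metabolites[nz])))
  })
  K <- model@kcat
  enzymes <- lapply(seq_along(model@enzymes), function(i) {
    js <- which(K[i, ] != 0)
    e <- list(id = model@enzymes[i],
              kcats = as.list(stats::setNames(as.numeric(K[i, js]),
                                              model@reactions[js])))
    if (length(model@enzymeMw) && is.finite(model@enzymeMw[i]))
      e$mw <- model@enzymeMw[i]
    if (is.finite(model@enzymeUb[i])) e$ub <- model@enzymeUb[i]
    e
  })
  out <- list(metabolites = as.list(model@metabolites),
              reactions = reactions, enzymes = enzymes,
              pool_total = if (is.finite(model@poolTotal))
                model@poolTotal else NULL,
              biomass = model@biomassRxn)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

## Proteomics tables ------------------------------------------------------

#' Read a proteomics table (TSV)
#'
#' Expects columns `protein_id`, `abundance_mmol_per_gDW` and optionally
#' `condition`.  Abundances must be non-negative; duplicated protein ids
#' within a condition are collapsed by their mean.
#'
#' @param path TSV file path.
#' @return a data.frame with columns `protein_id`,
#'   `abundance_mmol_per_gDW`, `condition`.
#' @export
readProteomics <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "abundance_mmol_per_gDW")
  if (!all(need %in% names(df)))
    stop("proteomics table must have columns ",
         paste(need, collapse = ", "))
  if (is.null(df$condition)) df$condition <- "unspecified"
  proteomicsTable(df$protein_id, df$abundance_mmol_per_gDW, df$condition)
}

#' @rdname readProteomics
#' @param protein_id,abundance,condition column vectors.
#' @export
proteomicsTable <- function(protein_id, abundance,
                            condition = "unspecified") {
  abundance <- as.numeric(abundance)
  if (any(!is.finite(abundance)) || any(abundance < 0))
    stop("abundances must be finite and non-negative")
  df <- data.frame(protein_id = as.character(protein_id),
                   abundance_mmol_per_gDW = abundance,
                   condition = as.character(condition),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("protein_id", "condition")])) {
    df <- stats::aggregate(
      abundance_mmol_per_gDW ~ protein_id + condition, data = df,
      FUN = mean)
    df <- df[c("protein_id", "abundance_mmol_per_gDW", "condition")]
  }
  df[order(df$condition, df$protein_id), , drop = FALSE]
}

#' @rdname readProteomics
#' @param table a proteomics data.frame as returned by [proteomicsTable()].
#' @export
writeProteomics <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## turn a (single-condition) proteomics table into a named vector
.proteomicsVector <- function(prot, condition = NULL) {
  if (!is.null(condition)) prot <- prot[prot$condition == condition, ]
  stats::setNames(prot$abundance_mmol_per_gDW, prot$protein_id)
}

## Condition YAML ---------------------------------------------------------

#' Read / write condition constraints (YAML)
#'
#' Keys: `mu`, `uptakes` (map reaction -> bound), `protein_content`,
#' `enzyme_total`, `growth_flex`, `bound_flex_step`, `max_flex_rounds`,
#' `label`.
#'
#' @param path YAML file path.
#' @return [readCondition()] returns a [ConditionConstraints-class].
#' @export
readCondition <- function(path) {
  y <- yaml::read_yaml(path)
  ConditionConstraints(
    mu = y$mu,
    uptakeBounds = if (length(y$uptakes))
      unlist(y$uptakes) else numeric(),
    proteinContent = y$protein_content %||% NA_real_,
    enzymeTotal = y$enzyme_total %||% NA_real_,
    growthFlex = y$growth_flex %||% 0.05,
    boundFlexStep = y$bound_flex_step %||% 0.01,
    maxFlexRounds = y$max_flex_rounds %||% 200L,
    label = y$label %||% "condition")
}

#' @rdname readCondition
#' @param cond a [ConditionConstraints-class].
#' @export
writeCondition <- function(cond, path) {
  y <- list(mu = cond@mu, uptakes = as.list(cond@uptakeBounds),
            protein_content = cond@proteinContent,
            enzyme_total = cond@enzymeTotal,
            growth_flex = cond@growthFlex,
            bound_flex_step = cond@boundFlexStep,
            max_flex_rounds = cond@maxFlexRounds, label = cond@label)
  yaml::write_yaml(y, path)
  invisible(path)
}

## GECKO-dialect SBML -----------------------------------------------------

#' Import a GECKO-dialect SBML model
#'
#' Reads an SBML (level 3, fbc) file in the GECKO encoding, where enzymes
#' appear as pseudo-metabolites (prefix `prot_`) with stoichiometric
#' coefficients \eqn{-1/kcat} in the reactions they catalyse, are supplied
#' by usage reactions (prefix `draw_prot_`), and the aggregate pool is an
#' exchange reaction (`prot_pool_exchange`).  The importer strips the
#' pseudo-metabolite layer and re-expresses it in the explicit form: a
#' coefficient \eqn{-1/k} on enzyme row \eqn{i} in reaction \eqn{j} becomes
#' `kcat[i, j] = k`; the pool exchange upper bound becomes the model's
#' `poolTotal`; a finite usage-reaction bound becomes the enzyme's
#' abundance upper bound; the `prot_pool` coefficient of a usage reaction,
#' when present, is taken as the enzyme's molecular weight.
#'
#' @param path SBML file.
#' @param enzymePrefix,usagePrefix,poolReaction identifier conventions of
#'   the dialect.
#' @param biomassRxn biomass reaction id; by default the first reaction
#'   whose id or name matches `"biomass|growth"` (case-insensitive).
#' @param kcatUnit `"per_h"` (GECKO convention; no conversion) or
#'   `"per_s"` (converted to h\eqn{^{-1}} by a factor 3600).
#' @return an [EnzymeConstrainedModel-class].
#' @export
importGeckoSBML <- function(path, enzymePrefix = "prot_",
                            usagePrefix = "draw_prot_",
                            poolReaction = "prot_pool_exchange",
                            biomassRxn = NULL,
                            kcatUnit = c("per_h", "per_s")) {
  kcatUnit <- match.arg(kcatUnit)
  doc <- xml2::read_xml(path)
  sp <- xml2::xml_find_all(doc, "//*[local-name()='species']")
  spId <- xml2::xml_attr(sp, "id")
  params <- xml2::xml_find_all(doc, "//*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rx <- xml2::xml_find_all(doc, "//*[local-name()='reaction']")
  rxId <- xml2::xml_attr(rx, "id")
  rxName <- xml2::xml_attr(rx, "name")
  stoich <- lapply(rx, .sbmlStoich)
  bounds <- t(vapply(rx, .sbmlBounds, numeric(2), pval = pval))
  poolMet <- sub("_$", "", paste0(enzymePrefix, "pool"))
  isEnzMet <- startsWith(spId, enzymePrefix) & spId != poolMet
  enzMet <- spId[isEnzMet]
  enzymes <- substring(enzMet, nchar(enzymePrefix) + 1L)
  isUsage <- startsWith(rxId, usagePrefix) | rxId == poolReaction
  if (is.null(biomassRxn)) {
    cand <- which(grepl("biomass|growth", rxId, ignore.case = TRUE) |
                    grepl("biomass|growth", rxName, ignore.case = TRUE))
    if (!length(cand))
      stop(errorCondition("no biomass reaction found",
                          class = c("parrot_structure", "error")))
    biomassRxn <- rxId[cand[1L]]
  } else if (!(biomassRxn %in% rxId)) {
    stop(errorCondition(paste("biomass reaction not in model:", biomassRxn),
                        class = c("parrot_structure", "error")))
  }
  ## harvest kcats, usage bounds and MWs
  kc <- NULL; eub <- stats::setNames(rep(Inf, length(enzymes)), enzymes)
  mw <- stats::setNames(rep(NA_real_, length(enzymes)), enzymes)
  poolTotal <- NA_real_
  conv <- if (kcatUnit == "per_s") 3600 else 1
  for (k in seq_along(rx)) {
    st <- stoich[[k]]
    if (rxId[k] == poolReaction) {
      poolTotal <- bounds[k, 2L]
      next
    }
    if (startsWith(rxId[k], usagePrefix)) {
      e <- substring(rxId[k], nchar(usagePrefix) + 1L)
      if (e %in% enzymes) {
        if (is.finite(bounds[k, 2L]) && bounds[k, 2L] < 1000)
          eub[e] <- bounds[k, 2L]
        if (poolMet %in% names(st)) mw[e] <- abs(st[[poolMet]])
      }
      next
    }
    enz <- intersect(names(st), enzMet)
    for (em in enz) {
      coef <- st[[em]]
      if (coef > 0)
        stop(errorCondition(
          sprintf("enzyme metabolite %s produced by non-usage reaction %s",
                  em, rxId[k]),
          class = c("parrot_dialect", "error")))
      kc <- rbind(kc, data.frame(
        enzyme = substring(em, nchar(enzymePrefix) + 1L),
        reaction = rxId[k], kcat = conv * (-1 / coef),
        stringsAsFactors = FALSE))
    }
  }
  keepR <- !isUsage
  mets <- setdiff(spId, c(enzMet, poolMet))
  S <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(length(mets), sum(keepR)),
                            dimnames = list(mets, rxId[keepR]))
  jj <- 0L
  for (k in which(keepR)) {
    jj <- jj + 1L
    st <- stoich[[k]]
    keep <- intersect(names(st), mets)
    if (length(keep))
      S[match(keep, mets), jj] <- unlist(st[keep])
  }
  EnzymeConstrainedModel(
    metabolites = mets, reactions = rxId[keepR], S = S,
    lb = bounds[keepR, 1L], ub = bounds[keepR, 2L],
    biomassRxn = biomassRxn, enzymes = enzymes, kcat = kc,
    poolTotal = poolTotal, enzymeMw = mw, enzymeUb = eub)
}

.sbmlStoich <- function(rnode) {
  refs <- xml2::xml_find_all(
    rnode, "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']")
  prods <- xml2::xml_find_all(
    rnode, "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']")
  getS <- function(nodes, sign) {
    if (!length(nodes)) return(numeric())
    s <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
    s[is.na(s)] <- 1
    stats::setNames(sign * s, xml2::xml_attr(nodes, "species"))
  }
  out <- c(getS(refs, -1), getS(prods, 1))
  if (!length(out)) return(list())
  as.list(tapply(out, names(out), sum))
}

.sbmlBounds <- function(rnode, pval) {
  at <- xml2::xml_attrs(rnode)
  pick <- function(key, default) {
    hit <- grep(paste0("(^|:)", key, "$"), names(at))
    if (length(hit)) {
      ref <- at[[hit[1L]]]
      if (ref %in% names(pval)) return(pval[[ref]])
      v <- suppressWarnings(as.numeric(ref))
      if (is.finite(v)) return(v)
    }
    default
  }
  reversible <- identical(at[["reversible"]], "true")
  c(pick("lowerFluxBound", if (reversible) -1000 else 0),
    pick("upperFluxBound", 1000))
}

#' Export a model as GECKO-dialect SBML
#'
#' Writes the explicit model back into the GECKO pseudo-metabolite
#' encoding (level 3 version 1 with fbc bounds): each enzyme becomes a
#' `prot_` species consumed at \eqn{1/kcat} by the reactions it catalyses
#' and supplied by a `draw_prot_` reaction whose upper bound is the
#' enzyme's abundance bound; a finite pool total becomes the
#' `prot_pool_exchange` bound.  [importGeckoSBML()] inverts this exactly.
#'
#' @param model an [EnzymeConstrainedModel-class].
#' @param path output file.
#' @inheritParams importGeckoSBML
#' @return `path`, invisibly.
#' @export
exportGeckoSBML <- function(model, path, enzymePrefix = "prot_",
                            usagePrefix = "draw_prot_",
                            poolReaction = "prot_pool_exchange") {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  poolMet <- sub("_$", "", paste0(enzymePrefix, "pool"))
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1" fbc:required="false">')
  w('<model id="%s" fbc:strict="true">', esc("pcmodel"))
  ## parameters for every distinct bound
  bnds <- unique(c(model@lb, model@ub, model@enzymeUb[is.finite(model@enzymeUb)],
                   if (is.finite(model@poolTotal)) model@poolTotal, 0, 1000))
  fmt1 <- function(v) format(v, digits = 17, trim = TRUE,
                             scientific = FALSE)
  pid <- stats::setNames(sprintf("FB%d", seq_along(bnds)),
                         vapply(bnds, fmt1, ""))
  pref <- function(v) pid[[fmt1(v)]]
  w('<listOfParameters>')
  for (i in seq_along(bnds))
    w('<parameter id="FB%d" value="%s" constant="true"/>', i,
      fmt1(bnds[i]))
  w('</listOfParameters>')
  w('<listOfSpecies>')
  for (m in model@metabolites)
    w('<species id="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>', esc(m))
  for (e in model@enzymes)
    w('<species id="%s%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>', enzymePrefix, esc(e))
  if (is.finite(model@poolTotal))
    w('<species id="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>', poolMet)
  w('</listOfSpecies>')
  w('<listOfReactions>')
  K <- model@kcat
  for (j in seq_along(model@reactions)) {
    w('<reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      esc(model@reactions[j]),
      if (model@lb[j] < 0) "true" else "false",
      pref(model@lb[j]), pref(model@ub[j]))
    nz <- which(model@S[, j] != 0)
    enzHere <- which(K[, j] != 0)
    react <- c(
      stats::setNames(-as.numeric(model@S[nz, j][model@S[nz, j] < 0]),
                      model@metabolites[nz][model@S[nz, j] < 0]),
      stats::setNames(1 / as.numeric(K[enzHere, j]),
                      paste0(enzymePrefix, model@enzymes)[enzHere]))
    prod <- stats::setNames(as.numeric(model@S[nz, j][model@S[nz, j] > 0]),
                            model@metabolites[nz][model@S[nz, j] > 0])
    if (length(react)) {
      w('<listOfReactants>')
      for (i in seq_along(react))
        w('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          esc(names(react)[i]), fmt1(react[i]))
      w('</listOfReactants>')
    }
    if (length(prod)) {
      w('<listOfProducts>')
      for (i in seq_along(prod))
        w('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          esc(names(prod)[i]), fmt1(prod[i]))
      w('</listOfProducts>')
    }
    w('</reaction>')
  }
  for (i in seq_along(model@enzymes)) {
    ubi <- model@enzymeUb[i]
    w('<reaction id="%s%s" reversible="false" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      usagePrefix, esc(model@enzymes[i]), pref(0),
      pref(if (is.finite(ubi)) ubi else 1000))
    if (is.finite(model@poolTotal)) {
      w('<listOfReactants>')
      w('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
        poolMet,
        format(if (length(model@enzymeMw) && is.finite(model@enzymeMw[i]))
          model@enzymeMw[i] else 1, digits = 17))
      w('</listOfReactants>')
    }
    w('<listOfProducts>')
    w('<speciesReference species="%s%s" stoichiometry="1" constant="true"/>',
      enzymePrefix, esc(model@enzymes[i]))
    w('</listOfProducts>')
    w('</reaction>')
  }
  if (is.finite(model@poolTotal)) {
    w('<reaction id="%s" reversible="false" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      poolReaction, pref(0), pref(model@poolTotal))
    w('<listOfProducts>')
    w('<speciesReference species="%s" stoichiometry="1" constant="true"/>',
      poolMet)
    w('</listOfProducts>')
    w('</reaction>')
  }
  w('</listOfReactions>')
  w('</model>')
  w('</sbml>')
  invisible(path)
}
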