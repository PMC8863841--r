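# Controlled subclass vocabulary. `n_chains` is the number of fatty-acyl
# chains a fully resolved molecular species of the subclass carries; NA means
# the subclass is only ever annotated at the sum-composition level.
.lipid_vocab <- data.frame(
  subclass = c("PC", "PE", "Cer", "LPE", "PA", "PG", "PI", "PS", "SM",
               "DG", "LPC", "So", "TG", "GM1", "LPA", "LPI", "LPG", "MG"),
  n_chains = c(2L, 2L, 2L, 1L, 2L, 2L, 2L, 2L, 2L,
               2L, 1L, 1L, 3L, NA, 1L, 1L, 1L, 1L),
  stringsAsFactors = FALSE
)

.geometry_map <- c(DG = "cone", PA = "cone", TG = "cone",
                   PC = "cylinder", PI = "cylinder",
                   LPI = "inverted_cone", LPC = "inverted_cone")

#' Supported lipid subclass codes
#'
#' @return Character vector of subclass abbreviations the parser accepts
#'   (PC, PE, Cer, DG, TG, the lyso classes, ...).
#' @export
lipid_subclasses <- function() .lipid_vocab$subclass

.parse_error <- function(msg, name) {
  stop(sprintf("cannot parse lipid name '%s': %s", name, msg), call. = FALSE)
}

.parse_chain <- function(chain, name, pos) {
  m <- regexec("^(O-|P-)?([0-9]+):([0-9]+)(e|p)?$", chain)
  parts <- regmatches(chain, m)[[1]]
  if (length(parts) == 0)
    .parse_error(sprintf(
      "malformed chain specification '%s' at character %d (expected <carbons>:<double bonds>)",
      chain, pos), name)
  linkage <- "ester"
  if (parts[2] == "O-" || parts[5] == "e") linkage <- "ether_o"
  if (parts[2] == "P-" || parts[5] == "p") linkage <- "ether_p"
  list(carbons = as.integer(parts[3]),
       double_bonds = as.integer(parts[4]),
       linkage = linkage)
}

#' Parse a lipid shorthand name
#'
#' Converts a LipidSearch-style shorthand name such as `"DG(22:6/22:6)"` or
#' `"PC(34:2)"` into a structured annotation. Chains separated by `/` are
#' sn-resolved and by `_` unresolved; both parse identically here apart from
#' the recorded separator. A single chain given for a multi-chain subclass is
#' treated as a sum composition (`level = "species_total"`); ether/plasmalogen
#' chains may be written `O-16:0`, `P-18:0`, `16:0e` or `18:0p` and are
#' recorded in `linkage` without altering the double-bond totals.
#'
#' @param name Lipid shorthand name. Whitespace around the subclass token is
#'   tolerated; subclass tokens are case-sensitive.
#' @return An object of class `lipid_annotation`: a list with `raw_name`,
#'   `subclass`, `chains` (data frame of `carbons`, `double_bonds`,
#'   `linkage`), `level` (`"molecular_species"` or `"species_total"`),
#'   `sn_resolved`, `total_carbons`, `total_double_bonds`.
#' @examples
#' parse_lipid_name("DG(22:6/22:6)")$total_carbons  # 44
#' parse_lipid_name("PC(34:2)")$level               # "species_total"
#' @export
parse_lipid_name <- function(name) {
  if (!is.character(name) || length(name) != 1 || is.na(name) || !nzchar(trimws(name)))
    stop("`name` must be a single nonempty string", call. = FALSE)
  raw <- name
  name <- trimws(name)
  m <- regexec("^([A-Za-z0-9]+)[ ]*\\((.*)\\)$", name)
  parts <- regmatches(name, m)[[1]]
  if (length(parts) == 0)
    .parse_error("expected '<subclass>(<chains>)'", raw)
  token <- parts[2]
  inside <- parts[3]
  if (!token %in% .lipid_vocab$subclass)
    .parse_error(sprintf("unknown lipid subclass token '%s'", token), raw)
  if (!nzchar(inside))
    .parse_error("empty chain specification", raw)
  sn_resolved <- grepl("/", inside, fixed = TRUE)
  chain_txt <- trimws(strsplit(inside, "[/_]")[[1]])
  # character position of each chain inside the original string, for errors
  base <- regexpr("(", name, fixed = TRUE) + 1L
  offsets <- cumsum(c(0L, nchar(chain_txt) + 1L))[seq_along(chain_txt)]
  chains <- lapply(seq_along(chain_txt), function(i)
    .parse_chain(chain_txt[i], raw, base + offsets[i]))
  chains <- data.frame(
    carbons = vapply(chains, `[[`, integer(1), "carbons"),
    double_bonds = vapply(chains, `[[`, integer(1), "double_bonds"),
    linkage = vapply(chains, `[[`, character(1), "linkage"),
    stringsAsFactors = FALSE
  )
  expected <- .lipid_vocab$n_chains[.lipid_vocab$subclass == token]
  if (is.na(expected)) {                      # sum-composition-only subclass
    if (nrow(chains) != 1)
      .parse_error(sprintf("subclass %s is annotated at the sum-composition level only", token), raw)
    level <- "species_total"
  } else if (nrow(chains) == expected) {
    level <- "molecular_species"
  } else if (nrow(chains) == 1L && expected > 1L) {
    level <- "species_total"
  } else {
    .parse_error(sprintf("subclass %s expects %d chain(s), found %d",
                         token, expected, nrow(chains)), raw)
  }
  structure(list(
    raw_name = raw,
    subclass = token,
    chains = chains,
    level = level,
    sn_resolved = sn_resolved,
    total_carbons = sum(chains$carbons),
    total_double_bonds = sum(chains$double_bonds)
  ), class = "lipid_annotation")
}

#' @export
print.lipid_annotation <- function(x, ...) {
  cat(sprintf("<lipid_annotation> %s  [%s, %s]  C%d:%d\n",
              x$raw_name, x$subclass, x$level,
              x$total_carbons, x$total_double_bonds))
  invisible(x)
}

#' Format a lipid annotation back into shorthand
#'
#' Inverse of [parse_lipid_name()] for round-tripping: a parsed
#' `molecular_species` annotation formats to a name that re-parses to an
#' equal annotation.
#'
#' @param annotation A `lipid_annotation`.
#' @return Shorthand string.
#' @export
format_lipid_name <- function(annotation) {
  stopifnot(inherits(annotation, "lipid_annotation"))
  ch <- annotation$chains
  pre <- ifelse(ch$linkage == "ether_o", "O-",
                ifelse(ch$linkage == "ether_p", "P-", ""))
  txt <- paste0(pre, ch$carbons, ":", ch$double_bonds)
  sep <- if (annotation$sn_resolved) "/" else "_"
  paste0(annotation$subclass, "(", paste(txt, collapse = sep), ")")
}

#' Annotate a vector of lipid names
#'
#' @param names Character vector of shorthand names.
#' @return Data frame with one row per name: `name`, `subclass`, `level`,
#'   `n_chains`, `total_carbons`, `total_double_bonds`.
#' @export
annotate_species <- function(names) {
  anns <- lapply(names, parse_lipid_name)
  data.frame(
    name = names,
    subclass = vapply(anns, `[[`, character(1), "subclass"),
    level = vapply(anns, `[[`, character(1), "level"),
    n_chains = vapply(anns, function(a) nrow(a$chains), integer(1)),
    total_carbons = vapply(anns, `[[`, integer(1), "total_carbons"),
    total_double_bonds = vapply(anns, `[[`, integer(1), "total_double_bonds"),
    stringsAsFactors = FALSE
  )
}

#' Molecular geometry class of a lipid subclass
#'
#' Classifies subclasses by the size ratio of hydrophilic head to
#' hydrophobic tail: cone (small head, two or more tails: DG, PA, TG),
#' cylinder (large head, two tails: PC, PI), inverted cone (large head,
#' single tail: LPI, LPC). Subclasses outside these three sets map to
#' `"unclassified"`; the mapping is total.
#'
#' @param subclass Character vector of subclass codes.
#' @return Character vector in
#'   `{"cone","cylinder","inverted_cone","unclassified"}`.
#' @examples
#' geometry_class(c("DG", "LPC", "SM"))
#' @export
geometry_class <- function(subclass) {
  out <- unname(.geometry_map[subclass])
  out[is.na(out)] <- "unclassified"
  out
}
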