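# Hierarchical haplotype nomenclature for hosts and tumours, and
# donor-haplotype reconstruction.
#
# Host names: <haplogroup>_<serial> (e.g. "A1_1"), or "unassigned".
# Tumour names: "CTVT_" + clade digit + up to five hierarchical levels
# of alternating numbers and letters (3 numbers, 2 letters, e.g.
# "CTVT_1A1a1"); the first letter level is upper case, the second lower
# case. A non-hierarchical "_<serial>" suffix distinguishes haplotypes
# only once all five levels are occupied: "CTVT_1A1a1_2" is legal,
# "CTVT_1A_1" is not (that haplotype would be "CTVT_1A1").

#' Parse and validate a tumour haplotype name
#'
#' @param name Character scalar, e.g. `"CTVT_1A1a1_2"`.
#' @return List with `clade`, `levels` (character vector of level
#'   tokens), `serial` (integer or `NA`). Errors on malformed names,
#'   including a serial suffix before all five levels are occupied.
#' @export
parse_tumour_name <- function(name) {
  if (!grepl("^CTVT_", name)) .stopf("tumour name must start with 'CTVT_': %s", name)
  body <- sub("^CTVT_", "", name)
  m <- regmatches(body, regexec(
    "^([0-9]+)([A-Z])?([0-9]+)?([a-z])?([0-9]+)?(?:_([0-9]+))?$", body))[[1]]
  if (!length(m)) .stopf("malformed tumour haplotype name: %s", name)
  tokens <- m[2:6]
  serial <- m[7]
  present <- tokens != ""
  # levels must be occupied left to right with no gaps
  if (any(diff(present) > 0)) {
    .stopf("malformed tumour haplotype name (level gap): %s", name)
  }
  if (serial != "" && !all(present)) {
    .stopf("serial suffix before all five levels are occupied: %s", name)
  }
  list(clade = tokens[1L], levels = tokens[present],
       serial = if (serial == "") NA_integer_ else as.integer(serial))
}

#' Is a tumour haplotype name valid?
#' @param name Character scalar.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_tumour_name <- function(name) {
  !inherits(tryCatch(parse_tumour_name(name), error = identity), "error")
}

#' Haplogroup definitions
#'
#' @param nodes List of lists, each with `name` (hierarchy position,
#'   e.g. `"A1"` for hosts or `"1A1"` for tumours), optional `parent`
#'   (defaults to the longest proper prefix among the other nodes), and
#'   `variants` (diagnostic variant keys specific to this node).
#' @param merged Optional character vector of node names flagged as
#'   indistinguishable from a sibling after site exclusions.
#' @return Object of class `HaplogroupDefinitions`.
#' @export
haplogroup_definitions <- function(nodes, merged = character()) {
  names_all <- vapply(nodes, `[[`, character(1L), "name")
  if (anyDuplicated(names_all)) .stopf("duplicate haplogroup names")
  for (i in seq_along(nodes)) {
    if (is.null(nodes[[i]]$parent)) {
      prefixes <- names_all[names_all != names_all[i] &
                              startsWith(names_all[i], names_all)]
      nodes[[i]]$parent <- if (length(prefixes))
        prefixes[which.max(nchar(prefixes))] else NA_character_
    }
    if (!is.na(nodes[[i]]$parent) && !(nodes[[i]]$parent %in% names_all)) {
      .stopf("parent '%s' of '%s' is not defined",
             nodes[[i]]$parent, names_all[i])
    }
  }
  names(nodes) <- names_all
  structure(list(nodes = nodes, merged = merged),
            class = "HaplogroupDefinitions")
}

# diagnostics of a node plus all its ancestors
#' @noRd
.cumulative_diagnostics <- function(defs, name) {
  out <- character()
  depth <- 0L
  while (!is.na(name)) {
    node <- defs$nodes[[name]]
    out <- c(out, node$variants)
    name <- node$parent
    depth <- depth + 1L
    if (depth > length(defs$nodes)) .stopf("cycle in haplogroup parents")
  }
  unique(out)
}

# deepest node whose cumulative diagnostics are all present
#' @noRd
.deepest_match <- function(defs, variant_keys) {
  best <- NA_character_
  best_depth <- -1L
  for (name in names(defs$nodes)) {
    diag <- .cumulative_diagnostics(defs, name)
    if (all(diag %in% variant_keys)) {
      depth <- nchar(name)
      if (depth > best_depth) {
        best <- name
        best_depth <- depth
      }
    }
  }
  best
}

#' Assign host haplotype names
#'
#' Each host is placed in the deepest haplogroup whose diagnostic
#' variants (its own plus its ancestors') are all present in the host's
#' filtered germline variant list. Within each haplogroup, distinct
#' variant sets receive serial numbers in order of first appearance
#' after a canonical sort by sample id, so the naming is independent of
#' input order. Hosts matching no haplogroup are `"unassigned"`.
#'
#' @param variant_sets Named list: per host sample, character vector of
#'   germline variant keys.
#' @param definitions A [haplogroup_definitions()].
#' @return Data frame: `sample_id`, `haplogroup`, `name`.
#' @export
assign_host_haplotype <- function(variant_sets, definitions) {
  ids <- sort(names(variant_sets))
  serials <- list()   # haplogroup -> list(set_key -> serial)
  rows <- lapply(ids, function(id) {
    keys <- variant_sets[[id]]
    grp <- .deepest_match(definitions, keys)
    if (is.na(grp)) {
      return(data.frame(sample_id = id, haplogroup = "unassigned",
                        name = "unassigned", stringsAsFactors = FALSE))
    }
    set_key <- paste(sort(unique(keys)), collapse = "|")
    if (is.null(serials[[grp]])) serials[[grp]] <<- list()
    if (is.null(serials[[grp]][[set_key]])) {
      serials[[grp]][[set_key]] <<- length(serials[[grp]]) + 1L
    }
    data.frame(sample_id = id, haplogroup = grp,
               name = paste0(grp, "_", serials[[grp]][[set_key]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign tumour haplotype names
#'
#' Places each tumour at the deepest matching node of the tumour
#' hierarchy for its clade and renders the name with the `"CTVT_"`
#' prefix. Distinct variant sets sharing a fully-occupied (five-level)
#' terminal group are distinguished with non-hierarchical serial
#' suffixes assigned in canonical (sample-id) order; names at
#' shallower nodes never carry a serial.
#'
#' @param variant_sets Named list: per tumour, character vector of
#'   variant keys.
#' @param clades Named character vector tumour id -> clade digit.
#' @param hierarchy A [haplogroup_definitions()] whose node names are
#'   hierarchy positions without the `"CTVT_"` prefix (e.g. `"1A1a1"`);
#'   the clade digit alone (e.g. `"3"`) is the clade root.
#' @return Data frame: `sample_id`, `clade`, `group`, `name`; every
#'   name satisfies [is_valid_tumour_name()].
#' @export
assign_tumour_haplotype <- function(variant_sets, clades, hierarchy) {
  ids <- sort(names(variant_sets))
  serials <- list()
  rows <- lapply(ids, function(id) {
    clade <- as.character(clades[[id]])
    if (!clade %in% as.character(1:9)) {
      .stopf("clade must be a single digit, got '%s'", clade)
    }
    keys <- variant_sets[[id]]
    # restrict to this clade's subtree
    sub_nodes <- Filter(function(n) startsWith(n$name, clade),
                        hierarchy$nodes)
    grp <- clade
    if (length(sub_nodes)) {
      defs <- haplogroup_definitions(unname(sub_nodes))
      hit <- .deepest_match(defs, keys)
      if (!is.na(hit)) grp <- hit
    }
    full_depth <- is_valid_tumour_name(paste0("CTVT_", grp, "_1"))
    name <- paste0("CTVT_", grp)
    if (full_depth) {
      set_key <- paste(sort(unique(keys)), collapse = "|")
      if (is.null(serials[[grp]])) serials[[grp]] <<- list()
      if (is.null(serials[[grp]][[set_key]])) {
        serials[[grp]][[set_key]] <<- length(serials[[grp]]) + 1L
      }
      name <- paste0(name, "_", serials[[grp]][[set_key]])
    }
    if (!is_valid_tumour_name(name)) {
      .stopf("constructed invalid tumour name: %s", name)
    }
    data.frame(sample_id = id, clade = clade, group = grp, name = name,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reconstruct the donor haplotype of a clade
#'
#' The inferred mtDNA haplotype captured at the clade's founding
#' horizontal-transfer event: the union of the clade-defining germline
#' substitutions and the clade-level potential-somatic substitutions.
#' Used to root per-clade trees and as the comparison haplotype.
#'
#' @param classified A `ClassifiedVariantSet`.
#' @param clade Clade id.
#' @return Sorted character vector of variant keys.
#' @export
reconstruct_donor_haplotype <- function(classified, clade) {
  clade <- as.character(clade)
  if (!clade %in% names(classified$clades)) {
    .stopf("clade '%s' not present in classified set", clade)
  }
  s <- classified$clades[[clade]]
  sort(union(s$clade_defining, s$potential_somatic))
}
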