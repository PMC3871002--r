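#' Read a model from the package's TSV reaction-table dialect
#'
#' The dialect is one row per reaction with columns `id`, `name`,
#' `stoichiometry` (e.g. `"-1 DA_c, +1 DA_v"`), `lower_bound`,
#' `upper_bound`, `boundary_kind`, `speed_tag`, `best_reference_flux`,
#' `groups` (semicolon-separated labels; the ASCII alias `aSYN` is accepted
#' for the Greek-alpha labels). Metabolite metadata travels in header
#' comment lines of the form
#' `#@ metabolite <TAB> id <TAB> name <TAB> compartment <TAB> is_currency`;
#' metabolites that appear in stoichiometries without such a line get a
#' cytosolic non-currency default record.
#'
#' @param source file path or connection.
#' @param provenance provenance string recorded on the model.
#' @return a validated `cell_model`.
#' @export
read_reaction_table <- function(source, provenance = "curated-skeleton") {
  lines <- readLines(source, encoding = "UTF-8")
  met_rows <- list()
  body <- character()
  body_lineno <- integer()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "#@ metabolite\t")) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) != 5)
        stop("format error: line ", i, ": metabolite header needs 5 fields")
      met_rows[[length(met_rows) + 1L]] <-
        metabolite(f[2], f[3], f[4], identical(f[5], "TRUE"))
    } else if (!startsWith(ln, "#") && nzchar(trimws(ln))) {
      body <- c(body, ln)
      body_lineno <- c(body_lineno, i)
    }
  }
  if (!length(body)) stop("format error: no reaction rows")
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  required <- c("id", "name", "stoichiometry", "lower_bound", "upper_bound",
                "boundary_kind", "speed_tag", "best_reference_flux", "groups")
  if (!all(required %in% header))
    stop("format error: line ", body_lineno[1], ": missing column(s): ",
         paste(setdiff(required, header), collapse = ", "))
  reactions <- list()
  seen <- character()
  for (k in seq_along(body)[-1]) {
    lineno <- body_lineno[k]
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    length(f) <- length(header)
    f[is.na(f)] <- ""
    row <- stats::setNames(as.list(f), header)
    if (row$id %in% seen)
      stop("format error: line ", lineno, ": duplicate reaction id '",
           row$id, "'")
    seen <- c(seen, row$id)
    st <- parse_stoichiometry(row$stoichiometry, lineno)
    grp <- if (nzchar(row$groups))
      normalize_group_label(trimws(strsplit(row$groups, ";", fixed = TRUE)[[1]]))
    else character()
    reactions[[length(reactions) + 1L]] <- reaction(
      id = row$id, name = row$name, stoichiometry = st,
      lower_bound = as.numeric(row$lower_bound),
      upper_bound = as.numeric(row$upper_bound),
      boundary_kind = row$boundary_kind, speed_tag = row$speed_tag,
      best_reference_flux = if (nzchar(row$best_reference_flux))
        as.numeric(row$best_reference_flux) else NA_real_,
      groups = grp)
  }
  met <- if (length(met_rows)) do.call(rbind, met_rows) else
    data.frame(id = character(), name = character(),
               compartment = character(), is_currency = logical())
  referenced <- unique(unlist(lapply(reactions,
                                     function(r) names(r$stoichiometry))))
  for (id in setdiff(referenced, met$id)) met <- rbind(met, metabolite(id))
  cell_model(met, reactions, provenance = provenance)
}

#' @noRd
parse_stoichiometry <- function(token, lineno = NA) {
  parts <- trimws(strsplit(token, ",", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (!length(parts))
    stop("format error: line ", lineno, ": empty stoichiometry")
  st <- numeric()
  for (p in parts) {
    m <- regmatches(p, regexec("^([+-]?[0-9]*\\.?[0-9]+)\\s+(\\S+)$", p))[[1]]
    if (length(m) != 3)
      stop("format error: line ", lineno,
           ": unparseable stoichiometry token '", p, "'")
    st[m[3]] <- st[m[3]] %||% 0
    st[m[3]] <- st[m[3]] + as.numeric(m[2])
  }
  st
}

#' @noRd
`%||%` <- function(a, b)
  if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b else a

# shortest decimal representation that re-reads to exactly x
#' @noRd
format_lossless <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(if (is.infinite(v)) "Inf" else "")
    for (d in c(6, 10, 15, 17)) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, "")
}

#' Write a model in the TSV reaction-table dialect
#'
#' Deterministic (model-ordered) output; reading the result back yields a
#' model equal to the input on every field except provenance. Greek-alpha
#' group labels are written with the ASCII alias `aSYN`.
#'
#' @param model a `cell_model`.
#' @param sink file path or connection.
#' @export
write_reaction_table <- function(model, sink) {
  stopifnot(inherits(model, "cell_model"))
  num <- format_lossless
  out <- character()
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    out <- c(out, paste("#@ metabolite", m$id, m$name, m$compartment,
                        m$is_currency, sep = "\t"))
  }
  out <- c(out, paste(c("id", "name", "stoichiometry", "lower_bound",
                        "upper_bound", "boundary_kind", "speed_tag",
                        "best_reference_flux", "groups"), collapse = "\t"))
  for (r in model$reactions) {
    st <- paste(sprintf("%s %s", sub("^([0-9])", "+\\1",
                                     format_lossless(r$stoichiometry)),
                        names(r$stoichiometry)), collapse = ", ")
    grp <- paste(gsub("αSYN", "aSYN", r$groups, fixed = TRUE), collapse = ";")
    out <- c(out, paste(r$id, r$name, st, num(r$lower_bound),
                        num(r$upper_bound), r$boundary_kind, r$speed_tag,
                        if (is.finite(r$best_reference_flux))
                          num(r$best_reference_flux) else "",
                        grp, sep = "\t"))
  }
  writeLines(out, sink, useBytes = FALSE)
  invisible(sink)
}
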