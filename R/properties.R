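#' @useDynLib ballhist, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

#' The twenty canonical amino-acid types
#'
#' Three-letter codes in title case (`"Ala"`, `"Arg"`, ...), the residue
#' vocabulary used throughout the package.
#'
#' @return A character vector of length 20.
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() {
  c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
    "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")
}

# Charge classes under physiological conditions: Arg and Lys carry a positive
# charge, Asp and Glu a negative one; everything else is grouped as neutral.
.positive_set <- c("Arg", "Lys")
.negative_set <- c("Asp", "Glu")

# Polar membership is convention-dependent; this default groups the uncharged
# polar side chains plus His and Cys. Override via property_table() if a
# different convention is wanted.
.polar_set <- c("Ser", "Thr", "Asn", "Gln", "Tyr", "Cys", "His")

#' Boolean amino-acid property tables
#'
#' A property table maps each Boolean amino-acid property name to the set of
#' residue types satisfying it. The default table contains the 20 identity
#' properties (one singleton per amino acid, named after it) plus four class
#' properties: `Positive` (Arg, Lys), `Negative` (Asp, Glu), `Neutral` (the
#' remaining 16 types), and `Polar` (Ser, Thr, Asn, Gln, Tyr, Cys, His).
#' Every residue type belongs to exactly one of the three charge classes.
#'
#' `property_table()` builds a table from scratch, validating that any
#' supplied properties use canonical residue codes. `read_property_table()`
#' reads one from a YAML file whose top level maps property names to lists of
#' codes; `write_property_table()` is its inverse.
#'
#' @param properties A named list of character vectors (property name ->
#'   residue types). Defaults to the class properties described above.
#'   Identity properties are always included.
#' @return A named list of character vectors with class `bh_property_table`.
#' @export
#' @examples
#' tab <- default_property_table()
#' tab$Positive
property_table <- function(properties = list(
                             Positive = .positive_set,
                             Negative = .negative_set,
                             Neutral = setdiff(amino_acids(), c(.positive_set, .negative_set)),
                             Polar = .polar_set
                           )) {
  aa <- amino_acids()
  identity <- stats::setNames(lapply(aa, function(a) a), aa)
  if (length(properties)) {
    if (is.null(names(properties)) || any(!nzchar(names(properties)))) {
      abort("all properties must be named", class = "bh_error_config")
    }
    bad <- setdiff(unlist(properties), aa)
    if (length(bad)) {
      abort(paste0("unknown residue codes in property table: ",
                   paste(unique(bad), collapse = ", ")),
            class = "bh_error_config")
    }
    if ("weight" %in% names(properties)) {
      abort("'weight' is a reserved name and cannot be a property",
            class = "bh_error_config")
    }
  }
  tab <- c(identity, lapply(properties, function(x) unique(as.character(x))))
  if (anyDuplicated(names(tab))) {
    abort("duplicated property names", class = "bh_error_config")
  }
  structure(tab, class = c("bh_property_table", "list"))
}

#' @rdname property_table
#' @export
default_property_table <- function() {
  property_table()
}

#' @rdname property_table
#' @param path Path to a YAML file.
#' @export
read_property_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("property table file not found: ", path), class = "bh_error_parse")
  }
  raw <- yaml::read_yaml(path)
  # identity properties are implicit; keep only class properties from file
  raw <- raw[!names(raw) %in% amino_acids()]
  property_table(lapply(raw, as.character))
}

#' @rdname property_table
#' @param table A `bh_property_table`.
#' @export
write_property_table <- function(table, path) {
  stopifnot(inherits(table, "bh_property_table"))
  classes <- table[!names(table) %in% amino_acids()]
  yaml::write_yaml(lapply(classes, as.list), path)
  invisible(path)
}

#' Does a residue type satisfy a Boolean property?
#'
#' @param res_type Character vector of canonical residue codes (`"Arg"` style).
#' @param property A single property name present in `table`.
#' @param table A property table from [property_table()].
#' @return A logical vector, `TRUE` where the residue type is in the
#'   property's set.
#' @export
#' @examples
#' satisfies("Arg", "Positive")
#' satisfies(c("Gly", "Lys"), "Arg")
satisfies <- function(res_type, property, table = default_property_table()) {
  if (length(property) != 1L || !property %in% names(table)) {
    abort(paste0("unknown property: ", paste(property, collapse = ", ")),
          class = "bh_error_config")
  }
  res_type %in% table[[property]]
}

#' Default property pool for template search
#'
#' The ordered list of candidate properties searched over when discovering
#' templates: the 20 identity properties followed by the class properties of
#' the table (24 properties for the default table).
#'
#' @param table A property table.
#' @return A character vector of property names, in table order.
#' @export
default_pool <- function(table = default_property_table()) {
  names(table)
}

# Membership matrix: residues x properties, 0/1. Rows follow `res_types`.
property_matrix <- function(res_types, pool, table) {
  m <- vapply(pool, function(p) as.integer(res_types %in% table[[p]]),
              integer(length(res_types)))
  if (length(res_types) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, pool))
  m
}

validate_template <- function(template, table, max_length = Inf) {
  template <- as.character(template)
  if (length(template) < 1L) {
    abort("template must contain at least one property", class = "bh_error_config")
  }
  if (anyDuplicated(template)) {
    abort("template properties must be distinct", class = "bh_error_config")
  }
  bad <- setdiff(template, names(table))
  if (length(bad)) {
    abort(paste0("unknown template properties: ", paste(bad, collapse = ", ")),
          class = "bh_error_config")
  }
  if (length(template) > max_length) {
    abort("template exceeds maximum length", class = "bh_error_config")
  }
  template
}
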