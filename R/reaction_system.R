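#' Reaction product with an optional delay
#'
#' @param species species id (character scalar).
#' @param stoich stoichiometry, a positive integer.
#' @param delay a [delay_spec()]; the default is an instantaneous product.
#' @return an object of class `ssa_product`.
#' @export
product <- function(species, stoich = 1L, delay = delay_zero()) {
  stopifnot(is.character(species), length(species) == 1L,
            inherits(delay, "delay_spec"))
  stoich <- as.integer(stoich)
  if (is.na(stoich) || stoich < 1L) stop("product stoichiometry must be >= 1")
  structure(list(species = species, stoich = stoich, delay = delay),
            class = "ssa_product")
}

#' Mass-action reaction with delayed products
#'
#' Reactions are at most second order. The propensity is the rate constant
#' times the product of reactant counts (for a doubled reactant A + A the
#' standard combinatorial count x(x-1)/2 is used). Each product carries a
#' [delay_spec()]; delayed products are placed on the simulator's waiting
#' list when the reaction fires and only released into the system once
#' their delay has elapsed. When a delayed product has stoichiometry > 1,
#' each copy draws its own delay.
#'
#' @param rate rate constant (s^-1, or s^-1 molecule^-1 for second order).
#' @param reactants named integer vector of stoichiometries, e.g.
#'   `c(Pro = 1)`; use `character()`/`NULL` for a source reaction.
#' @param products list of [product()] objects (possibly empty).
#' @return an object of class `ssa_reaction`.
#' @examples
#' reaction(0.028, c(Pro = 1),
#'          list(product("Pro", delay = delay_constant(19)),
#'               product("RBS", delay = delay_constant(2))))
#' @export
reaction <- function(rate, reactants = NULL, products = list()) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate <= 0)
    stop("rate constant must be a single positive number")
  if (is.null(reactants)) reactants <- integer(0)
  if (length(reactants) > 0 &&
      (is.null(names(reactants)) || any(!nzchar(names(reactants)))))
    stop("reactants must be a named vector of stoichiometries")
  reactants <- vapply(reactants, as.integer, integer(1))
  if (any(reactants < 1L)) stop("reactant stoichiometry must be >= 1")
  if (sum(reactants) > 2L) stop("reactions are at most second order")
  if (!all(vapply(products, inherits, logical(1), "ssa_product")))
    stop("products must be a list of product() objects")
  structure(list(rate = rate, reactants = reactants, products = products),
            class = "ssa_reaction")
}

#' Reaction system for the delayed stochastic simulator
#'
#' @param reactions list of [reaction()] objects.
#' @param initial_counts named non-negative integer vector of initial
#'   molecule counts; species not mentioned by any reaction may appear.
#' @param species optional explicit species ordering; defaults to the union
#'   of species in `initial_counts` and the reactions, in first-seen order.
#' @return an object of class `reaction_system`.
#' @export
reaction_system <- function(reactions, initial_counts = integer(0),
                            species = NULL) {
  if (!all(vapply(reactions, inherits, logical(1), "ssa_reaction")))
    stop("reactions must be a list of reaction() objects")
  used <- unique(unlist(lapply(reactions, function(r)
    c(names(r$reactants),
      vapply(r$products, function(p) p$species, character(1))))))
  if (is.null(species)) species <- unique(c(names(initial_counts), used))
  if (!all(used %in% species))
    stop("species referenced by a reaction missing from the species list: ",
         paste(setdiff(used, species), collapse = ", "))
  init <- stats::setNames(integer(length(species)), species)
  if (length(initial_counts)) {
    if (is.null(names(initial_counts)))
      stop("initial_counts must be named")
    bad <- setdiff(names(initial_counts), species)
    if (length(bad)) stop("unknown species in initial_counts: ",
                          paste(bad, collapse = ", "))
    ic <- vapply(initial_counts, as.integer, integer(1))
    if (any(is.na(ic) | ic < 0L)) stop("initial counts must be >= 0")
    init[names(initial_counts)] <- ic
  }
  structure(list(species = species, reactions = reactions,
                 initial_counts = init),
            class = "reaction_system")
}

#' @export
print.reaction_system <- function(x, ...) {
  cat(sprintf("reaction_system: %d species, %d reactions\n",
              length(x$species), length(x$reactions)))
  fmt_side <- function(named) {
    if (!length(named)) return("0")
    paste(ifelse(named > 1L, paste0(named, " "), ""), names(named),
          sep = "", collapse = " + ")
  }
  for (r in x$reactions) {
    prods <- if (!length(r$products)) "0" else
      paste(vapply(r$products, function(p) {
        tag <- switch(p$delay$kind, zero = "",
                      constant = sprintf("(%g)", p$delay$mean),
                      gamma = sprintf("(gamma %g,%g)", p$delay$mean, p$delay$sd))
        paste0(if (p$stoich > 1L) paste0(p$stoich, " ") else "", p$species, tag)
      }, character(1)), collapse = " + ")
    cat(sprintf("  %s --(%g)--> %s\n", fmt_side(r$reactants), r$rate, prods))
  }
  cat("  initial: ",
      paste(names(x$initial_counts), x$initial_counts, sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# serializable plain-list form used for YAML round trips
system_to_list <- function(sys) {
  list(
    species = as.list(sys$species),
    initial_counts = as.list(sys$initial_counts),
    reactions = lapply(sys$reactions, function(r) list(
      rate = r$rate,
      reactants = as.list(r$reactants),
      products = lapply(r$products, function(p) list(
        species = p$species, stoich = p$stoich,
        delay = list(kind = p$delay$kind, mean = p$delay$mean,
                     sd = p$delay$sd))))))
}

system_from_list <- function(x) {
  rx <- lapply(x$reactions, function(r) {
    reac <- unlist(r$reactants)
    if (is.null(reac)) reac <- integer(0)
    reaction(r$rate, reac, lapply(r$products, function(p) {
      d <- p$delay
      product(p$species, p$stoich,
              delay_spec(d$kind, mean = as.numeric(d$mean),
                         sd = as.numeric(d$sd)))
    }))
  })
  init <- unlist(x$initial_counts)
  if (is.null(init)) init <- integer(0)
  reaction_system(rx, init, species = unlist(x$species))
}

#' Read or write a reaction system as a YAML config
#'
#' @param sys a [reaction_system()].
#' @param path file path of the YAML document.
#' @return `read_reaction_system` returns a `reaction_system`;
#'   `write_reaction_system` returns `path` invisibly.
#' @export
write_reaction_system <- function(sys, path) {
  stopifnot(inherits(sys, "reaction_system"))
  yaml::write_yaml(system_to_list(sys), path)
  invisible(path)
}

#' @rdname write_reaction_system
#' @export
read_reaction_system <- function(path) {
  system_from_list(yaml::read_yaml(path))
}
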