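# Product archetypes: the two reference children's products used for
# exposure scenarios. A pacifier stands for products meant to be mouthed
# long-term, a doll for products mouthed occasionally.

#' Default product archetype table
#'
#' Geometry of the two reference products. The mouthing contact area of
#' 10 cm^2 is the typical mouthing area of children; slab thickness and the
#' product/saliva volumes are SYNTHETIC representative defaults (a thin
#' silicone pacifier nipple; a PVC doll wall), fully overridable via
#' [read_archetype_table()].
#'
#' @return Named list of archetypes (class `archetype_table`); each entry
#'   has `name`, `material_default`, `d_p` (cm), `v_p` (cm^3), `v_f`
#'   (cm^3), `a_contact` (cm^2).
#' @export
default_archetype_table <- function() {
  structure(list(
    pacifier = list(name = "pacifier", material_default = "silicone",
                    d_p = 0.25, v_p = 10, v_f = 10, a_contact = 10),
    doll     = list(name = "doll", material_default = "PVC",
                    d_p = 0.20, v_p = 50, v_f = 10, a_contact = 10)
  ), class = "archetype_table")
}

#' Read / write a product archetype table (YAML)
#'
#' One document per archetype with fields `name`, `material_default`,
#' `d_p_cm`, `v_p_cm3`, `v_f_cm3`, `a_contact_cm2`.
#'
#' @param path Path to a YAML file.
#' @export
read_archetype_table <- function(path) {
  docs <- yaml::read_yaml(path)
  tbl <- lapply(docs, function(d) {
    geom <- list(name = d$name, material_default = d$material_default,
                 d_p = d$d_p_cm, v_p = d$v_p_cm3, v_f = d$v_f_cm3,
                 a_contact = d$a_contact_cm2)
    if (any(unlist(geom[c("d_p", "v_p", "v_f", "a_contact")]) <= 0))
      stop_domain("archetype '", d$name, "': all dimensions must be positive")
    geom
  })
  names(tbl) <- vapply(tbl, `[[`, character(1), "name")
  structure(tbl, class = "archetype_table")
}

#' @rdname read_archetype_table
#' @param table An `archetype_table` to serialize.
#' @export
write_archetype_table <- function(table, path) {
  stopifnot(inherits(table, "archetype_table"))
  docs <- lapply(unname(table), function(a) {
    list(name = a$name, material_default = a$material_default,
         d_p_cm = a$d_p, v_p_cm3 = a$v_p, v_f_cm3 = a$v_f,
         a_contact_cm2 = a$a_contact)
  })
  yaml::write_yaml(docs, path)
  invisible(path)
}

#' Allocate a material to a product archetype
#'
#' PVC, PP and wood observations are modelled as dolls; silicone and EVA as
#' pacifiers. An explicit archetype on the record overrides the rule.
#'
#' @param material Material name.
#' @param override Optional explicit archetype (`"pacifier"`/`"doll"`);
#'   honoured when non-`NA`.
#' @return `"pacifier"` or `"doll"`.
#' @export
allocate_product <- function(material, override = NA_character_) {
  if (length(override) == 1 && !is.na(override) && nzchar(override)) {
    if (!override %in% c("pacifier", "doll"))
      stop_domain("unknown product archetype override '", override, "'")
    return(override)
  }
  switch(material,
         PVC = , PP = , wood = "doll",
         silicone = , EVA = "pacifier",
         stop_unsupported_material(material))
}
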