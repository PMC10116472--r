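# Bundled Schema.org core snapshot. This is a curated miniature of the real
# vocabulary — enough classes to root every Outbreak class at Thing, with a
# small, representative property payload per class (not the full Schema.org
# inventory). It is the single source of Schema.org truth in this package;
# nothing is fetched from the network.

SCHEMA_ORG_IRI <- "https://schema.org/"

core_prop <- function(name, domain, range = "schema:Text", description = "") {
  property_definition(paste0("schema:", name),
                      domain_includes = paste0("schema:", domain),
                      range_includes = range,
                      description = description)
}

#' The bundled Schema.org core vocabulary snapshot
#'
#' A deterministic, self-contained miniature of Schema.org: a single class
#' hierarchy rooted at `schema:Thing` covering the classes the Outbreak
#' schema extends from (`Dataset`, `MedicalStudy`, `HowTo`,
#' `SoftwareApplication`, ...), each with a small curated property set that
#' includes the Thing-level `name`, `description`, `identifier` and `url`.
#' `MedicalTrial` and `MedicalObservationalStudy` are included (they differ
#' only in `trialDesign` vs `studyDesign`) even though the Outbreak schema
#' does not extend them.
#'
#' @return A [schema_document()] with namespace `"schema"`.
#' @export
core_vocabulary <- function() {
  ctx <- context_map(schema = SCHEMA_ORG_IRI)

  cls <- function(name, parent = NULL, description = "") {
    class_definition(paste0("schema:", name),
                     sub_class_of = if (is.null(parent)) character() else paste0("schema:", parent),
                     description = description)
  }

  classes <- list(
    cls("Thing", NULL, "The most generic type of item."),
    cls("CreativeWork", "Thing", "The most generic kind of creative work."),
    cls("MediaObject", "CreativeWork", "A media object such as a data file."),
    cls("Dataset", "CreativeWork", "A body of structured information."),
    cls("DataDownload", "MediaObject", "A dataset in downloadable form."),
    cls("MedicalEntity", "Thing", "The most generic medical entity."),
    cls("MedicalStudy", "MedicalEntity", "A medical study of human subjects."),
    cls("MedicalTrial", "MedicalStudy", "A medical trial with a control group."),
    cls("MedicalObservationalStudy", "MedicalStudy",
        "A medical study without intervention."),
    cls("MedicalScholarlyArticle", "CreativeWork", "A scholarly article in medicine."),
    cls("HowTo", "CreativeWork", "Instructions that explain how to achieve a result."),
    cls("SoftwareApplication", "CreativeWork", "A software application."),
    cls("Person", "Thing", "A person (alive, dead, undead, or fictional)."),
    cls("Organization", "Thing", "An organization such as a lab or NGO."),
    cls("MonetaryGrant", "Thing", "A monetary grant."),
    cls("Product", "Thing", "Any offered product or service."),
    cls("Place", "Thing", "Entities with a somewhat fixed physical extension."))

  properties <- list(
    core_prop("name", "Thing", description = "The name of the item."),
    core_prop("description", "Thing", description = "A description of the item."),
    core_prop("identifier", "Thing", description = "Any identifier, e.g. DOI."),
    core_prop("url", "Thing", "schema:URL", "URL of the item."),
    core_prop("alternateName", "Thing", description = "An alias for the item."),
    core_prop("author", "CreativeWork", c("schema:Person", "schema:Organization")),
    core_prop("citation", "CreativeWork", "schema:CreativeWork"),
    core_prop("datePublished", "CreativeWork", "schema:Date"),
    core_prop("keywords", "CreativeWork"),
    core_prop("license", "CreativeWork", c("schema:CreativeWork", "schema:URL")),
    core_prop("contentUrl", "MediaObject", "schema:URL"),
    core_prop("encodingFormat", "MediaObject"),
    core_prop("contentSize", "MediaObject"),
    core_prop("distribution", "Dataset", "schema:DataDownload"),
    core_prop("measurementTechnique", "Dataset"),
    core_prop("variableMeasured", "Dataset"),
    core_prop("temporalCoverage", "Dataset"),
    core_prop("spatialCoverage", "Dataset", "schema:Place"),
    core_prop("code", "MedicalEntity"),
    core_prop("guideline", "MedicalEntity"),
    core_prop("healthCondition", "MedicalStudy", "schema:MedicalEntity"),
    core_prop("sponsor", "MedicalStudy", c("schema:Person", "schema:Organization")),
    core_prop("status", "MedicalStudy"),
    core_prop("studySubject", "MedicalStudy", "schema:MedicalEntity"),
    core_prop("trialDesign", "MedicalTrial"),
    core_prop("studyDesign", "MedicalObservationalStudy"),
    core_prop("publicationType", "MedicalScholarlyArticle"),
    core_prop("step", "HowTo"),
    core_prop("estimatedCost", "HowTo"),
    core_prop("tool", "HowTo", "schema:Product"),
    core_prop("totalTime", "HowTo"),
    core_prop("applicationCategory", "SoftwareApplication"),
    core_prop("operatingSystem", "SoftwareApplication"),
    core_prop("softwareVersion", "SoftwareApplication"),
    core_prop("downloadUrl", "SoftwareApplication", "schema:URL"),
    core_prop("affiliation", "Person", "schema:Organization"),
    core_prop("email", "Person"),
    core_prop("familyName", "Person"),
    core_prop("givenName", "Person"),
    core_prop("legalName", "Organization"),
    core_prop("parentOrganization", "Organization", "schema:Organization"),
    core_prop("contactPoint", "Organization"),
    core_prop("amount", "MonetaryGrant"),
    core_prop("funder", "MonetaryGrant", c("schema:Person", "schema:Organization")),
    core_prop("fundedItem", "MonetaryGrant", "schema:Thing"),
    core_prop("manufacturer", "Product", "schema:Organization"),
    core_prop("model", "Product"),
    core_prop("productID", "Product"),
    core_prop("address", "Place"),
    core_prop("geo", "Place"),
    core_prop("containedInPlace", "Place", "schema:Place"))

  schema_document("schema", ctx, classes, properties)
}
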