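# Activity-coaching knowledge base and RDF/Turtle export. The schema links
# participants to health records, daily activity levels, step predictions
# (interval days), weekly statistics and received recommendations through a
# fixed set of object properties with declared domains and ranges. The
# exporter emits one triple per line, which is both valid Turtle and a
# profile the bundled reader can parse back for round-trip checks.

KB_PREFIX <- "http://stepcoach.local/schema#"

# object properties: name, domain, range, cardinality
kb_schema_properties <- function() {
  p <- rbind(
    c("HasPersonalHealthRecord", "Participant", "HealthRecord", "some"),
    c("HasPersonalDataInfo", "Participant", "PersonalData", "some"),
    c("HasPersonalPreferences", "Participant", "Preferences", "some"),
    c("HasReceivedPersonalRecommendation", "Participant", "Recommendation",
      "some"),
    c("HasHealthStatus", "Participant", "ParticipantStatus", "some"),
    c("HasbeenCollectedBy", "ActivityData", "ActivityDataValue", "some"),
    c("HasTimeStamp", "ActivityDataValue", "TemporalEntity", "some"),
    c("HasMeasurementCapability", "ActivityDevice",
      "MeasurementCapability", "only"),
    c("HasOutput", "ActivityDevice", "SensorOutput", "some"),
    c("Observes", "ActivityDevice", "Property", "only"),
    c("Detects", "ActivityDevice", "Stimulus", "only"),
    c("FeatureOfInterest", "Observation", "FeatureOfInterest", "only"),
    c("ObservationResult", "Observation", "SensorOutput", "only"),
    c("ObservedBy", "Observation", "Sensor", "only"),
    c("IsPropertyOf", "Property", "FeatureOfInterest", "some"),
    c("HasProperty", "FeatureOfInterest", "Property", "some"),
    c("HasIntervalDay", "Participant", "StepPrediction", "some"),
    c("HasActivityLevel", "Participant", "Activity_Level_Daily", "some"),
    c("HasStatValue", "Participant", "Statistical", "some")
  )
  data.frame(property = p[, 1], domain = p[, 2], range = p[, 3],
             cardinality = p[, 4], stringsAsFactors = FALSE)
}

#' Create an empty knowledge base
#'
#' @return a `knowledge_base` object holding the schema, the rule/message
#'   catalog and empty instance stores.
#' @export
kb_new <- function() {
  structure(list(schema = kb_schema_properties(),
                 catalog = message_catalog(),
                 participants = character(0),
                 levels = list(), predictions = list(),
                 stats = list(), recommendations = list()),
            class = "knowledge_base")
}

#' Annotate instances into the knowledge base
#'
#' `kb_add_participant` registers a participant; `kb_add_level` attaches a
#' daily activity level; `kb_add_prediction` attaches one interval-day step
#' prediction; `kb_add_stat` attaches a weekly statistic value;
#' `kb_add_recommendation` attaches a received recommendation with its
#' timestamp.
#'
#' @param kb a [kb_new()] knowledge base.
#' @param participant participant identifier.
#' @param date calendar date of the annotation.
#' @param level daily activity level code.
#' @return the updated knowledge base.
#' @export
kb_add_participant <- function(kb, participant) {
  kb$participants <- union(kb$participants, participant)
  kb
}

#' @rdname kb_add_participant
#' @export
kb_add_level <- function(kb, participant, date, level) {
  kb <- kb_add_participant(kb, participant)
  kb$levels[[length(kb$levels) + 1]] <-
    list(participant = participant, date = as.Date(date), level = level)
  kb
}

#' @param day horizon day index of the prediction.
#' @param point,lower,upper forecast point and interval bounds.
#' @rdname kb_add_participant
#' @export
kb_add_prediction <- function(kb, participant, date, day, point, lower,
                              upper) {
  kb <- kb_add_participant(kb, participant)
  kb$predictions[[length(kb$predictions) + 1]] <-
    list(participant = participant, date = as.Date(date), day = day,
         point = point, lower = lower, upper = upper)
  kb
}

#' @param name,value statistic name and numeric value.
#' @param week week index.
#' @rdname kb_add_participant
#' @export
kb_add_stat <- function(kb, participant, week, name, value) {
  kb <- kb_add_participant(kb, participant)
  kb$stats[[length(kb$stats) + 1]] <-
    list(participant = participant, week = week, name = name, value = value)
  kb
}

#' @param variable fired propositional variable id (e.g. `"A-8"`).
#' @param message rendered message text.
#' @rdname kb_add_participant
#' @export
kb_add_recommendation <- function(kb, participant, date, variable, message) {
  if (!variable %in% kb$catalog$id) {
    stop("cannot annotate undeclared variable: ", variable, call. = FALSE)
  }
  kb <- kb_add_participant(kb, participant)
  kb$recommendations[[length(kb$recommendations) + 1]] <-
    list(participant = participant, date = as.Date(date),
         variable = variable, message = message)
  kb
}

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub('"', '\\"', x, fixed = TRUE)
}

#' Export the knowledge base as RDF/Turtle
#'
#' Emits the schema (every object property declared with its domain and
#' range) followed by the instance triples: participants with their health
#' records, daily activity levels (`HasActivityLevel`), interval-day step
#' predictions (`HasIntervalDay`), weekly statistics (`HasStatValue`) and
#' received recommendations with timestamps (`HasTimeStamp`). One triple per
#' line, so any standard Turtle parser (and the bundled [parse_turtle()])
#' reads it back with a conserved triple count.
#'
#' @param kb a `knowledge_base`.
#' @param file optional path to write to.
#' @return the Turtle document as a single character string (invisibly when
#'   `file` is given).
#' @export
export_rdf <- function(kb, file = NULL) {
  stopifnot(inherits(kb, "knowledge_base"))
  ln <- c(
    sprintf("@prefix sc: <%s> .", KB_PREFIX),
    "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
    ""
  )
  s <- kb$schema
  for (i in seq_len(nrow(s))) {
    ln <- c(ln,
            sprintf("sc:%s rdf:type owl:ObjectProperty .", s$property[i]),
            sprintf("sc:%s rdfs:domain sc:%s .", s$property[i], s$domain[i]),
            sprintf("sc:%s rdfs:range sc:%s .", s$property[i], s$range[i]))
  }
  iri <- function(...) sprintf("sc:%s", gsub("[^A-Za-z0-9_]", "_",
                                             paste(..., sep = "_")))
  for (p in kb$participants) {
    ln <- c(ln,
            sprintf("%s rdf:type sc:Participant .", iri(p)),
            sprintf("%s sc:HasPersonalHealthRecord %s .", iri(p),
                    iri(p, "record")))
  }
  for (x in kb$levels) {
    node <- iri(x$participant, "level", format(x$date))
    ln <- c(ln,
            sprintf("%s sc:HasActivityLevel %s .", iri(x$participant), node),
            sprintf("%s sc:HasTimeStamp \"%s\"^^xsd:date .", node,
                    format(x$date)),
            sprintf("%s sc:levelCode \"%d\"^^xsd:integer .", node, x$level))
  }
  for (x in kb$predictions) {
    node <- iri(x$participant, "pred", format(x$date), x$day)
    ln <- c(ln,
            sprintf("%s sc:HasIntervalDay %s .", iri(x$participant), node),
            sprintf("%s sc:pointForecast \"%g\"^^xsd:double .", node,
                    x$point),
            sprintf("%s sc:lowerBound \"%d\"^^xsd:integer .", node,
                    as.integer(x$lower)),
            sprintf("%s sc:upperBound \"%d\"^^xsd:integer .", node,
                    as.integer(x$upper)))
  }
  for (x in kb$stats) {
    node <- iri(x$participant, "stat", x$week, x$name)
    ln <- c(ln,
            sprintf("%s sc:HasStatValue %s .", iri(x$participant), node),
            sprintf("%s sc:statName \"%s\" .", node, ttl_escape(x$name)),
            sprintf("%s sc:statValue \"%g\"^^xsd:double .", node, x$value))
  }
  for (i in seq_along(kb$recommendations)) {
    x <- kb$recommendations[[i]]
    node <- iri(x$participant, "reco", format(x$date), x$variable, i)
    ln <- c(ln,
            sprintf("%s sc:HasReceivedPersonalRecommendation %s .",
                    iri(x$participant), node),
            sprintf("%s sc:variableId \"%s\" .", node, x$variable),
            sprintf("%s sc:HasTimeStamp \"%s\"^^xsd:date .", node,
                    format(x$date)),
            sprintf("%s sc:messageText \"%s\" .", node,
                    ttl_escape(x$message)))
  }
  doc <- paste(ln, collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}

#' Parse a one-triple-per-line Turtle document
#'
#' Reads the profile emitted by [export_rdf()] (prefix directives plus one
#' `subject predicate object .` statement per line, objects possibly quoted
#' literals with datatype tags) into a triple table. Intended for round-trip
#' and query-style checks; it is not a general Turtle parser.
#'
#' @param text Turtle document as a string, or a file path.
#' @return data.frame with columns `subject`, `predicate`, `object`.
#' @export
parse_turtle <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text), collapse = "\n")
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@prefix") &
                   !startsWith(lines, "#")]
  m <- regmatches(lines,
                  regexec("^(\\S+)\\s+(\\S+)\\s+(.*?)\\s*\\.$", lines))
  bad <- lines[vapply(m, length, 1L) != 4]
  if (length(bad)) {
    stop("unparseable statement(s): ", paste(head(bad, 3), collapse = " | "),
         call. = FALSE)
  }
  data.frame(subject = vapply(m, `[`, "", 2),
             predicate = vapply(m, `[`, "", 3),
             object = vapply(m, `[`, "", 4),
             stringsAsFactors = FALSE)
}

#' Count the triples in a knowledge base export
#'
#' @param kb a `knowledge_base`.
#' @return number of statement triples the export will contain.
#' @export
kb_triple_count <- function(kb) {
  nrow(parse_turtle(export_rdf(kb)))
}

#' Look up objects by predicate (SPARQL-style single-pattern query)
#'
#' @param triples triple table from [parse_turtle()].
#' @param predicate predicate to match, e.g.
#'   `"sc:HasReceivedPersonalRecommendation"`.
#' @param subject optional subject filter.
#' @return character vector of matching objects.
#' @export
ttl_query <- function(triples, predicate, subject = NULL) {
  sel <- triples$predicate == predicate
  if (!is.null(subject)) sel <- sel & triples$subject == subject
  triples$object[sel]
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("Knowledge base:", length(x$participants), "participant(s),",
      length(x$levels), "level annotation(s),",
      length(x$predictions), "prediction(s),",
      length(x$stats), "statistic(s),",
      length(x$recommendations), "recommendation(s)\n")
  invisible(x)
}
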