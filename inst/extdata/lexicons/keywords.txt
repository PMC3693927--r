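# positive keywords signalling a resource description or head
database
ontology
web service
webservice
tool
toolkit
program
software
package
server
repository
resource
pipeline
suite
browser
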