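# weak contextual indicators (verbs and ambiguous heads, inflected forms
# listed explicitly so matching is plain case-insensitive token lookup)
record
recorded
records
recording
alignment
alignments
develop
developed
develops
developing
ran
run
runs
running
use
used
uses
using
interface
interfaces
platform
platforms
implemented
implement
implements
execute
executed
download
downloaded
install
installed
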