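# Example top-journal list (partial): the named members of the top-20 set
# used for the prestige index in the aspirin study; supply your own full
# list, one journal title per line.
JAMA
The Lancet
BMJ
Circulation
Blood
The European Heart Journal
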