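North
South
East
West
Greater
Upper
Lower
London
Midshire
Wessex
Mercia
Borders
Fenland
Riding
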