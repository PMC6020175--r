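Street
Road
Avenue
Lane
Drive
Court
Place
Square
Crescent
Gardens
Way
Close
Walk
Row
Hill
Green
Park
Mews
Rise
Grove
Vale
Terrace
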