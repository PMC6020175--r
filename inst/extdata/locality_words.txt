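Barkingford
Welthorpe
Granchester
Dunsfold
Eastleigh
Farnwick
Gorsely
Hatherton
Ilminster
Kelbrook
Langmere
Morthwaite
Nethercott
Oxcroft
Penhallow
Quenby
Redbourne
Silverdale
Thornbury
Ulverscroft
Wainfleet
Yarwell
Ambleworth
Bickerton
Cranfield
Droxford
Elmswell
Fenwick
Garsington
Holmfirth
Iverlea
Kempsford
Longstock
Millbrook
Netherby
Otterburn
Pangmoor
Rainford
Stanwick
Tilbrook
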