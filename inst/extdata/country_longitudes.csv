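country,longitude_deg
Austria,14.6
Belgium,4.5
Bosnia and Herzegovina,17.8
Bulgaria,25.5
Croatia,16.0
Estonia,25.0
Finland,26.0
France,2.2
Germany,10.4
Greece,22.0
Hungary,19.5
Italy,12.6
Luxembourg,6.1
Netherlands,5.3
Poland,19.1
Portugal,-8.2
Romania,25.0
Russia,37.6
Sardinia,9.1
Serbia,21.0
Slovakia,19.7
Slovenia,14.8
Spain,-3.7
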