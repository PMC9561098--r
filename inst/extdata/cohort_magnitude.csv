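model,category,cushion,reference,mean,ci_lower,ci_upper,label
elliptical,SkinProtection,ActaEmbrace,foam_3in,0.83,0.77,0.89,Superior
elliptical,SkinProtection,GelProElite,foam_3in,0.84,0.78,0.91,Comparable
elliptical,SkinProtection,GeoMattPRT,foam_3in,0.97,0.90,1.04,Comparable
elliptical,SkinProtection,J2,foam_3in,0.80,0.75,0.86,Superior
elliptical,SkinProtection,MatrxVI,foam_3in,0.87,0.81,0.93,Comparable
elliptical,SkinProtection,RideForward,foam_3in,0.70,0.66,0.75,Superior
trigonometric,SkinProtection,ActaEmbrace,foam_3in,0.84,0.80,0.88,Superior
trigonometric,SkinProtection,GelProElite,foam_3in,0.98,0.92,1.04,Comparable
trigonometric,SkinProtection,GeoMattPRT,foam_3in,0.95,0.89,1.01,Comparable
trigonometric,SkinProtection,J2,foam_3in,0.78,0.74,0.82,Superior
trigonometric,SkinProtection,MatrxVI,foam_3in,0.96,0.91,1.01,Comparable
trigonometric,SkinProtection,RideForward,foam_3in,0.75,0.71,0.78,Superior
elliptical,GeneralUse,Amara100,foam_2in,0.97,0.91,1.04,Comparable
elliptical,GeneralUse,CrossCut,foam_2in,1.14,1.06,1.23,Comparable
elliptical,GeneralUse,GelUSeatLite,foam_2in,0.95,0.89,1.02,Comparable
elliptical,GeneralUse,MedlineGel,foam_2in,1.20,1.11,1.29,Inferior
trigonometric,GeneralUse,Amara100,foam_2in,0.92,0.87,0.97,Comparable
trigonometric,GeneralUse,CrossCut,foam_2in,1.03,0.96,1.10,Comparable
trigonometric,GeneralUse,GelUSeatLite,foam_2in,0.74,0.70,0.78,Superior
trigonometric,GeneralUse,MedlineGel,foam_2in,1.18,1.11,1.25,Inferior
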